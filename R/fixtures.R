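#' Random transcript with controlled GC content
#'
#' I.i.d. nucleotides with `P(G) + P(C) = gc`, split evenly within the
#' GC and AU pairs. Fully reproducible from the seed.
#'
#' @param length sequence length (>= 22 for a scannable transcript).
#' @param gc GC fraction in \[0, 1\] (default 0.5).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return RNA string.
#' @export
synth_transcript <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  with_seed(seed, {
    paste(sample(RNA_BASES, length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}

#' Random 22-nt guide strands
#' @param n number of guides.
#' @inheritParams synth_transcript
#' @param length guide length (default 22).
#' @return character vector of guides.
#' @export
synth_guides <- function(n, gc = 0.5, seed = NULL, length = 22L) {
  with_seed(seed, {
    m <- matrix(sample(RNA_BASES, n * length, replace = TRUE,
                       prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  })
}

#' Synthetic guide/activity dataset with known generating model
#'
#' Emulates the statistical shape of a sensor-assay activity table:
#' random 22-mer guides whose latent ln-activity is the generating model's
#' score plus Gaussian noise on the ln scale. The reported percent
#' activity is `exp(ln_activity)` clipped to `[clip[1], clip[2]]`; clipped
#' records carry a flag and the latent `ln_activity` column is kept so
#' parameter-recovery analyses are not distorted by the clip (see the
#' package vignette: under the built-in model the percent scale saturates
#' at the lower clip for most random guides).
#'
#' @param n number of records.
#' @param coeffs generating model (default the built-in `"table2"`).
#' @param noise_sd Gaussian noise sd on the ln scale (default 1.0).
#' @param gc guide GC content (default 0.5).
#' @param seed RNG seed.
#' @param motif_fraction fraction of guides into which a forbidden motif
#'   is planted at a random position (default 0).
#' @param motif the motif planted (default "UGGC").
#' @param clip percent-scale clip (default `c(0.5, 100)`).
#' @param params an [nn_params()] set.
#' @return data.frame with `guide_seq`, `silencing_percent`,
#'   `ln_activity` (latent), `clipped`, `source`.
#' @export
synth_activity_dataset <- function(n, coeffs = mirscan_model("table2"),
                                   noise_sd = 1.0, gc = 0.5, seed = NULL,
                                   motif_fraction = 0, motif = "UGGC",
                                   clip = c(0.5, 100),
                                   params = nn_params()) {
  stopifnot(n >= 1, noise_sd >= 0, motif_fraction >= 0, motif_fraction <= 1)
  coeffs <- mirscan_model(coeffs)
  with_seed(seed, {
    guides <- synth_guides(n, gc)
    if (motif_fraction > 0) {
      planted <- which(stats::runif(n) < motif_fraction)
      for (i in planted) {
        at <- sample.int(22L - nchar(motif) + 1L, 1L)
        substr(guides[i], at, at + nchar(motif) - 1L) <- motif
      }
    }
    X <- feature_matrix(guides, params)
    if ("dG_self" %in% names(coeffs$terms)) {
      X <- cbind(X, dG_self = vapply(guides, function(g)
        fold_self_dG(g, params)$mfe_dG, numeric(1), USE.NAMES = FALSE))
    }
    ln_act <- score(X, coeffs) + stats::rnorm(n, sd = noise_sd)
    pct <- pmin(pmax(exp(ln_act), clip[1L]), clip[2L])
    data.frame(guide_seq = guides,
               silencing_percent = pct,
               ln_activity = ln_act,
               clipped = exp(ln_act) < clip[1L] | exp(ln_act) > clip[2L],
               source = "synthetic",
               stringsAsFactors = FALSE)
  })
}
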