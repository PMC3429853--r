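#' Enumerate every candidate target site of a transcript
#'
#' Slides a 22-nt window over the sense transcript; each window is a
#' target site and its guide strand is the exact reverse complement.
#' Coordinates are 1-based and inclusive on the sense strand, so a
#' transcript of length L yields L - 21 sites. Windows containing
#' non-ACGU characters (e.g. N) are skipped and counted, not errored.
#'
#' @param transcript RNA (or DNA; T is transcribed) sequence string.
#' @param id transcript identifier carried into the output.
#' @param site_length window length (default 22).
#' @return data.frame with `transcript_id`, `start`, `sense_seq`,
#'   `guide_seq`; attribute `n_skipped` counts ambiguous windows.
#' @examples
#' enumerate_candidates(strrep("A", 25), "toy")
#' @export
enumerate_candidates <- function(transcript, id = "transcript",
                                 site_length = 22L) {
  transcript <- rna_normalize(transcript, allow_other = TRUE)
  n <- nchar(transcript)
  if (n < site_length) {
    stop("transcript '", id, "' is shorter than ", site_length, " nt",
         call. = FALSE)
  }
  starts <- seq_len(n - site_length + 1L)
  sense <- substring(transcript, starts, starts + site_length - 1L)
  ok <- !grepl("[^ACGU]", sense)
  out <- data.frame(transcript_id = id, start = starts[ok],
                    sense_seq = sense[ok],
                    guide_seq = rna_revcomp(sense[ok]),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Scan transcripts for efficient shRNA guide candidates
#'
#' For every transcript in a FASTA file (or a named character vector of
#' sequences): enumerate all 22-nt target sites, derive guide strands,
#' compute duplex thermodynamics and position features, score with the
#' coefficient model, apply the configured artifact filters and the
#' optional duplex-stability gate, and rank surviving candidates by
#' descending predicted score (ties broken by position). Scores are on
#' the model's ln scale; `score_percent` is the exp-transformed
#' convenience column clipped to \[0, 100\].
#'
#' @param fasta path to a FASTA file (DNA or RNA), or a named character
#'   vector of sequences.
#' @param model a `coef_table`, `"table2"`, or a JSON path.
#' @param config a [filter_config()], or `NULL` to disable all filters.
#' @param dg_range optional length-2 numeric: survivors must have total
#'   duplex dG inside `[dg_range[1], dg_range[2]]` kcal/mol (the optimal
#'   stability window is `c(-35, -25)`); `NULL` (default) disables the
#'   gate and leaves the cubic dG terms of the model to do the work.
#' @param top_n keep only the `top_n` highest-ranked survivors.
#' @param out optional TSV path for the report.
#' @param keep_flagged keep filtered-out candidates in the result (rank
#'   NA) instead of dropping them (default TRUE; ignored under `top_n`).
#' @param corrections duplex dG convention, see [duplex_dG_total()].
#' @param params an [nn_params()] set.
#' @return data.frame with columns `transcript_id`, `start`, `sense_seq`,
#'   `guide_seq`, `dG`, `dG1`, `dG_self`, `score`, `score_percent`,
#'   `flags` ("PASS" or the failed filters), `rank` (1..k among
#'   survivors, NA otherwise); attributes `filter_counts` and
#'   `n_skipped`.
#' @export
scan_transcript <- function(fasta, model = "table2", config = filter_config(),
                            dg_range = NULL, top_n = NULL, out = NULL,
                            keep_flagged = TRUE, corrections = TRUE,
                            params = nn_params()) {
  coeffs <- mirscan_model(model)
  seqs <- if (length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readBStringSet(fasta)
    if (!length(ss)) stop("empty FASTA: ", fasta, call. = FALSE)
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    if (is.null(names(fasta))) {
      names(fasta) <- paste0("seq", seq_along(fasta))
    }
    fasta
  }
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase (masked) bases uppercased")
  }
  seqs <- vapply(seqs, rna_normalize, character(1), allow_other = TRUE)

  per_tx <- lapply(names(seqs), function(id) {
    enumerate_candidates(seqs[[id]], id)
  })
  cands <- do.call(rbind, per_tx)
  n_skipped <- sum(vapply(per_tx, attr, integer(1), which = "n_skipped"))
  if (!nrow(cands)) stop("no scorable candidate sites", call. = FALSE)

  X <- feature_matrix(cands$guide_seq, params, corrections = corrections)
  dG_self <- vapply(cands$guide_seq,
                    function(g) fold_self_dG(g, params)$mfe_dG,
                    numeric(1), USE.NAMES = FALSE)
  needs_self <- "dG_self" %in% names(coeffs$terms)
  if (needs_self) X <- cbind(X, dG_self = dG_self)
  scores <- score(X, coeffs)

  if (is.null(config)) {
    flags <- data.frame(motif = FALSE, complexity = FALSE,
                        self_structure = FALSE, seed_match = FALSE,
                        pass = TRUE)[rep(1L, nrow(cands)), , drop = FALSE]
    counts <- c(motif = 0L, complexity = 0L, self_structure = 0L,
                seed_match = 0L)
  } else {
    rep_ <- apply_filters(cands$guide_seq, config, params, dG_self = dG_self)
    flags <- rep_$flags
    counts <- rep_$counts
  }
  if (!is.null(dg_range)) {
    stopifnot(length(dg_range) == 2L, dg_range[1L] <= dg_range[2L])
    in_range <- X[, "dG"] >= dg_range[1L] & X[, "dG"] <= dg_range[2L]
    flags$dg_range <- !in_range
    flags$pass <- flags$pass & in_range
    counts <- c(counts, dg_range = sum(!in_range))
  }

  flag_str <- apply(flags[, setdiff(names(flags), "pass"), drop = FALSE], 1L,
                    function(r) if (any(r)) {
                      paste(names(r)[r], collapse = ",")
                    } else "PASS")
  res <- data.frame(cands, dG = unname(X[, "dG"]), dG1 = unname(X[, "dG1"]),
                    dG_self = dG_self, score = unname(scores),
                    score_percent = pmin(pmax(exp(scores), 0), 100),
                    flags = flag_str, pass = flags$pass,
                    stringsAsFactors = FALSE)
  # survivors ranked by descending score, stable position tie-break
  res <- res[order(-res$pass, -res$score, res$transcript_id, res$start), ]
  res$rank <- NA_integer_
  res$rank[res$pass] <- seq_len(sum(res$pass))
  if (!is.null(top_n)) {
    res <- res[res$pass & res$rank <= top_n, , drop = FALSE]
  } else if (!keep_flagged) {
    res <- res[res$pass, , drop = FALSE]
  }
  res$pass <- NULL
  rownames(res) <- NULL
  attr(res, "filter_counts") <- counts
  attr(res, "n_skipped") <- n_skipped
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
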