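#' Filter configuration for candidate guides
#'
#' Bundles the artifact/off-target filters applied before ranking:
#' forbidden sequence motifs (UGGC/GCCA are linked to cell-viability
#' artifacts; GGGG/UUUU/AAAA are low-complexity runs, and UUUU additionally
#' is an RNA polymerase III termination signal -- CCCC is deliberately NOT
#' on the default list because removing it was found not to help), a
#' DUST-style low-complexity score, a guide self-structure threshold, and
#' a miRNA seed-identity check.
#'
#' @param motifs character vector of forbidden substrings (RNA alphabet).
#' @param complexity_threshold DUST score above which a guide is flagged.
#' @param self_structure_threshold kcal/mol; guides folding below it (i.e.
#'   with a stable self-structure) are flagged. Default -2.
#' @param seed_region integer length-2 vector: guide positions of the seed
#'   (default 2:7, the canonical miRNA hexamer seed; 1:8 also supported).
#' @param seed_set character vector of seed sequences to avoid (e.g. from
#'   [read_mature_mirnas()]); `NULL` disables the seed filter.
#' @param motif,complexity,self_structure,seed_match logical enable flags.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(motifs = c("UGGC", "GCCA", "GGGG", "UUUU", "AAAA"),
                          complexity_threshold = 2.0,
                          self_structure_threshold = -2.0,
                          seed_region = c(2L, 7L),
                          seed_set = NULL,
                          motif = TRUE, complexity = TRUE,
                          self_structure = TRUE,
                          seed_match = !is.null(seed_set)) {
  stopifnot(length(seed_region) == 2L, seed_region[1L] <= seed_region[2L],
            is.finite(complexity_threshold))
  structure(list(motifs = rna_normalize(motifs),
                 complexity_threshold = complexity_threshold,
                 self_structure_threshold = self_structure_threshold,
                 seed_region = as.integer(seed_region),
                 seed_set = if (is.null(seed_set)) NULL
                            else unique(rna_normalize(seed_set)),
                 enabled = c(motif = motif, complexity = complexity,
                             self_structure = self_structure,
                             seed_match = seed_match)),
            class = "filter_config")
}

#' Flag guides containing forbidden motifs
#'
#' @param guide character vector of guide sequences.
#' @param motifs forbidden substrings.
#' @return logical vector; attribute `matched` lists the motifs found per
#'   guide (as a list).
#' @export
motif_flags <- function(guide,
                        motifs = c("UGGC", "GCCA", "GGGG", "UUUU", "AAAA")) {
  hits <- lapply(guide, function(g) motifs[vapply(motifs, grepl, logical(1),
                                                  x = g, fixed = TRUE)])
  flag <- lengths(hits) > 0L
  attr(flag, "matched") <- hits
  flag
}

#' DUST-style low-complexity score
#'
#' Classic triplet score: within each window of width `window`, count the
#' occurrences c_t of every 3-mer and compute `sum(c_t * (c_t - 1) / 2) /
#' (w - 3)` where `w` is the window width; the sequence score is the
#' maximum over windows (default: one window spanning the whole guide).
#' A homopolymer 22-mer scores 10; a sequence whose triplets are all
#' distinct scores 0.
#'
#' @param guide character vector of sequences.
#' @param window window width (default: full sequence length).
#' @param threshold flag when score > threshold (default 2).
#' @return numeric scores with attribute `flag` (logical, score >
#'   threshold).
#' @export
dust_score <- function(guide, window = NULL, threshold = 2.0) {
  one <- function(g) {
    n <- nchar(g)
    w <- if (is.null(window)) n else min(window, n)
    if (w < 4L) return(0)
    trip <- substring(g, seq_len(n - 2L), seq_len(n - 2L) + 2L)
    best <- 0
    for (s in seq_len(n - w + 1L)) {
      tw <- trip[s:(s + w - 3L)]
      ct <- table(tw)
      best <- max(best, sum(ct * (ct - 1) / 2) / (w - 3L))
    }
    best
  }
  sc <- vapply(guide, one, numeric(1), USE.NAMES = FALSE)
  attr(sc, "flag") <- sc > threshold
  sc
}

#' Flag guides whose seed matches a known miRNA seed
#'
#' Extracts the guide substring at `seed_region` (1-based positions along
#' the guide, default 2-7) and flags the guide when that substring is in
#' `seed_set`. An empty seed set disables the filter with a warning.
#'
#' @param guide character vector of guides.
#' @param seed_set character vector of seed strings (same region
#'   convention).
#' @param seed_region length-2 integer positions.
#' @return logical vector.
#' @export
seed_match <- function(guide, seed_set, seed_region = c(2L, 7L)) {
  if (is.null(seed_set) || !length(seed_set)) {
    warning("empty seed set; seed filter disabled")
    return(rep(FALSE, length(guide)))
  }
  seeds <- substr(guide, seed_region[1L], seed_region[2L])
  seeds %in% seed_set
}

#' Flag guides with stable intramolecular self-structure
#'
#' @param guide character vector of guides.
#' @param threshold kcal/mol; flagged when the MFE is strictly below it
#'   (default -2: a stable self-structure competes with target pairing).
#' @param params an [nn_params()] set.
#' @return logical vector with attribute `dG_self` (the MFE values).
#' @export
self_structure_flag <- function(guide, threshold = -2.0,
                                params = nn_params()) {
  dg <- vapply(guide, function(g) fold_self_dG(g, params)$mfe_dG,
               numeric(1), USE.NAMES = FALSE)
  flag <- dg < threshold
  attr(flag, "dG_self") <- dg
  flag
}

#' Apply all configured filters to a candidate list
#'
#' Evaluates every enabled filter independently (a candidate survives iff
#' it passes all of them), preserving input order among survivors. The
#' filters commute and the operation is idempotent.
#'
#' @param guides character vector of candidate guide sequences.
#' @param config a [filter_config()].
#' @param params an [nn_params()] set (for the self-structure filter).
#' @param dG_self optional precomputed self-structure energies (skips
#'   refolding).
#' @return object of class `filter_report`: list with `flags` (data.frame
#'   of per-candidate logicals: motif, complexity, self_structure,
#'   seed_match, pass), `counts` (removals per filter), `survivors`
#'   (indices into `guides`).
#' @export
apply_filters <- function(guides, config = filter_config(),
                          params = nn_params(), dG_self = NULL) {
  n <- length(guides)
  en <- config$enabled
  f_motif <- if (en[["motif"]]) {
    as.logical(motif_flags(guides, config$motifs))
  } else rep(FALSE, n)
  f_complex <- if (en[["complexity"]]) {
    attr(dust_score(guides, threshold = config$complexity_threshold), "flag")
  } else rep(FALSE, n)
  f_self <- if (en[["self_structure"]]) {
    if (is.null(dG_self)) {
      as.logical(self_structure_flag(guides,
                                     config$self_structure_threshold, params))
    } else dG_self < config$self_structure_threshold
  } else rep(FALSE, n)
  f_seed <- if (en[["seed_match"]]) {
    seed_match(guides, config$seed_set, config$seed_region)
  } else rep(FALSE, n)
  flags <- data.frame(motif = f_motif, complexity = f_complex,
                      self_structure = f_self, seed_match = f_seed)
  flags$pass <- !Reduce(`|`, flags)
  structure(list(flags = flags,
                 counts = vapply(flags[, 1:4, drop = FALSE], sum, integer(1)),
                 survivors = which(flags$pass)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", nrow(x$flags), " candidates, ",
      length(x$survivors), " pass\n", sep = "")
  cat("  flagged:", paste(names(x$counts), x$counts, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Read mature miRNA sequences and extract their seeds
#'
#' Reads a FASTA of mature miRNA sequences (miRBase dialect; U or T
#' alphabet accepted) and returns the unique seed strings under the given
#' region rule, ready to use as `seed_set` in [filter_config()].
#'
#' @param path FASTA file of mature miRNA sequences.
#' @param seed_region length-2 integer guide positions (default 2-7).
#' @return character vector of unique seed sequences.
#' @export
read_mature_mirnas <- function(path, seed_region = c(2L, 7L)) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- rna_normalize(as.character(ss), allow_other = TRUE)
  seeds <- substr(seqs, seed_region[1L], seed_region[2L])
  seeds <- seeds[nchar(seeds) == seed_region[2L] - seed_region[1L] + 1L &
                 !grepl("[^ACGU]", seeds)]
  unique(unname(seeds))
}
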