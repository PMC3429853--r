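GUIDE_LENGTH <- 22L

check_guide <- function(guide, length = GUIDE_LENGTH) {
  rna_check(guide, "guide")
  if (!is.null(length) && nchar(guide) != length) {
    stop("guide must be ", length, " nt, got ", nchar(guide), call. = FALSE)
  }
  invisible(guide)
}

#' Position-dependent one-hot encoding of a guide strand
#'
#' Records the guide in a numerical code: indicator `b_p` is 1 when base
#' `b` occupies position `p` (1-based from the guide 5' end). Indicators
#' are addressed by name (`A_1` ... `U_22`), never by column order, so the
#' encoding is unambiguous.
#'
#' @param guide 22-nt RNA string (guide strand, 5'->3').
#' @param length expected guide length (default 22).
#' @return named numeric vector of `4 * length` indicators with exactly
#'   `length` ones.
#' @examples
#' v <- one_hot(strrep("U", 22))
#' sum(v)  # 22
#' @export
one_hot <- function(guide, length = GUIDE_LENGTH) {
  check_guide(guide, length)
  n <- nchar(guide)
  b <- strsplit(guide, "", fixed = TRUE)[[1L]]
  out <- numeric(4L * n)
  names(out) <- as.vector(t(outer(RNA_BASES, seq_len(n), paste, sep = "_")))
  out[paste(b, seq_len(n), sep = "_")] <- 1
  out
}

# Indicator matrix for many guides at once: columns A_1 ... U_L.
one_hot_matrix <- function(guides, length = GUIDE_LENGTH) {
  m <- seq_to_matrix(guides)
  if (!is.null(length) && ncol(m) != length) {
    stop("guides must be ", length, " nt", call. = FALSE)
  }
  n <- ncol(m)
  cols <- as.vector(outer(RNA_BASES, seq_len(n),
                          function(b, p) paste(b, p, sep = "_")))
  out <- matrix(0, nrow = nrow(m), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (p in seq_len(n)) {
    for (bb in RNA_BASES) {
      out[, paste(bb, p, sep = "_")] <- as.numeric(m[, p] == bb)
    }
  }
  out
}

#' Assemble the full model feature vector for one guide
#'
#' Populates the position indicators and the requested thermodynamic terms:
#' total duplex free energy `dG` with its square `dG2` and cube `dG3`
#' (the non-linear duplex-stability terms), the first-dinucleotide stack
#' `dG1`, and optionally the full 21-entry stack profile and the
#' competing-structure energies `dG_self` (guide intramolecular MFE),
#' `dG_dimer` (guide self-dimer) and `dG_target` (local target structure;
#' requires `transcript` and `site_start`).
#'
#' @param guide 22-nt RNA guide strand.
#' @param params an [nn_params()] set.
#' @param thermo include dG/dG2/dG3/dG1 (default TRUE).
#' @param profile include the per-position stack profile dG_1..dG_21.
#' @param self_structure include `dG_self`.
#' @param dimer include `dG_dimer`.
#' @param corrections passed to [duplex_dG_total()].
#' @param transcript,site_start,window_flank when supplied, adds
#'   `dG_target` via [target_local_dG()].
#' @return named numeric vector (a flat feature row).
#' @export
build_feature_vector <- function(guide, params = nn_params(), thermo = TRUE,
                                 profile = FALSE, self_structure = FALSE,
                                 dimer = FALSE, corrections = TRUE,
                                 transcript = NULL, site_start = NULL,
                                 window_flank = 100L) {
  fv <- one_hot(guide)
  if (thermo) {
    dG <- duplex_dG_total(guide, params, corrections = corrections)
    prof <- duplex_dG_profile(guide, params)
    fv <- c(fv, dG = dG, dG2 = dG^2, dG3 = dG^3, dG1 = unname(prof[1L]))
    if (profile) fv <- c(fv, prof)
  }
  if (self_structure) {
    fv <- c(fv, dG_self = fold_self_dG(guide, params)$mfe_dG)
  }
  if (dimer) fv <- c(fv, dG_dimer = dimer_dG(guide, guide, params))
  if (!is.null(transcript) && !is.null(site_start)) {
    fv <- c(fv, dG_target = target_local_dG(transcript, site_start,
                                            window_flank, params))
  }
  fv
}

#' Feature matrix for a set of guides
#'
#' Vectorized companion of [build_feature_vector()] covering the terms the
#' regression models use (indicators + dG, dG2, dG3, dG1 and optionally the
#' stack profile and `dG_self`). One row per guide; columns are named like
#' the model terms.
#'
#' @param guides character vector of 22-nt guides.
#' @inheritParams build_feature_vector
#' @return numeric matrix with named columns.
#' @export
feature_matrix <- function(guides, params = nn_params(), thermo = TRUE,
                           profile = FALSE, self_structure = FALSE,
                           corrections = TRUE) {
  X <- one_hot_matrix(guides)
  if (thermo) {
    th <- duplex_features_bulk(guides, params, corrections = corrections)
    add <- cbind(dG = th$dG, dG2 = th$dG^2, dG3 = th$dG^3, dG1 = th$dG1)
    if (profile) {
      pm <- th$profile
      colnames(pm) <- paste0("dG_", seq_len(ncol(pm)))
      add <- cbind(add, pm)
    }
    X <- cbind(X, add)
  }
  if (self_structure) {
    X <- cbind(X, dG_self = vapply(guides, function(g)
      fold_self_dG(g, params)$mfe_dG, numeric(1), USE.NAMES = FALSE))
  }
  X
}

#' Drop the least-informative nucleotide indicator at every position
#'
#' The full one-hot matrix is redundant (the four indicators at a position
#' sum to 1). To remove the redundancy the model keeps three of the four
#' nucleotides per position, dropping the one whose indicator carries the
#' smallest absolute Pearson correlation with ln silencing activity --
#' i.e. the nucleotide with the lowest input to the efficiency score.
#' Ties are broken by the larger correlation p-value, then alphabetically.
#' For a 22-nt guide this leaves 66 retained indicators.
#'
#' @param dataset activity table (data.frame with `guide_seq` and
#'   `silencing_percent`, see [read_activity_table()]), or anything
#'   accepted by [activity_response()].
#' @param ln_floor floor (percent) applied before taking ln of activity.
#' @return object of class `reduced_matrix_spec`: list with `dropped`
#'   (named character vector, one base per position), `retained` (the 66
#'   retained column names) and `degenerate` (TRUE when activity was
#'   constant and the choice fell back to tie-breaks alone).
#' @export
reduce_matrix <- function(dataset, ln_floor = 0.5) {
  if (nrow(dataset) < 2L) stop("need at least 2 records", call. = FALSE)
  y <- activity_response(dataset, ln_floor)
  X <- one_hot_matrix(dataset$guide_seq)
  npos <- ncol(X) / 4L
  degenerate <- stats::sd(y) == 0
  cors <- correlate_features(X, y, ln = FALSE)
  dropped <- character(npos)
  for (p in seq_len(npos)) {
    cand <- paste(RNA_BASES, p, sep = "_")
    r <- abs(cors$R[cand])
    pv <- cors$p[cand]
    # order: smallest |R|, then larger p, then alphabetical (cand is sorted)
    ord <- order(r, -pv, cand)
    dropped[p] <- RNA_BASES[ord[1L]]
  }
  names(dropped) <- as.character(seq_len(npos))
  retained <- unlist(lapply(seq_len(npos), function(p) {
    paste(setdiff(RNA_BASES, dropped[p]), p, sep = "_")
  }))
  structure(list(dropped = dropped, retained = retained,
                 degenerate = degenerate),
            class = "reduced_matrix_spec")
}

#' @export
print.reduced_matrix_spec <- function(x, ...) {
  cat("<reduced_matrix_spec> ", length(x$retained), " retained indicators (",
      length(x$dropped), " positions x 3)\n", sep = "")
  cat("  dropped:", paste0(x$dropped, collapse = ""), "\n")
  if (x$degenerate) cat("  NOTE: constant activity; drops are tie-break only\n")
  invisible(x)
}

#' Write feature rows as a tab-separated table
#'
#' @param X feature matrix (or a single named vector).
#' @param path output file.
#' @export
write_feature_table <- function(X, path) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  utils::write.table(as.data.frame(X), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
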