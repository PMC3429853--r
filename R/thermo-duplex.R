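#' Per-position dinucleotide stack profile of a fully paired duplex
#'
#' For a guide strand paired with its exact complement, returns the
#' nearest-neighbor stack free energy at every dinucleotide position:
#' entry i is the stack formed by guide positions i and i+1 (1-based,
#' 5'->3' along the guide). These are the local duplex stabilities
#' dG_1 ... dG_(L-1).
#'
#' @param guide RNA string, length >= 2 (typically the 22-nt guide).
#' @param params an [nn_params()] set.
#' @return numeric vector of length `nchar(guide) - 1`, names `dG_1` ...
#' @export
duplex_dG_profile <- function(guide, params = nn_params()) {
  rna_check(guide, "guide")
  n <- nchar(guide)
  if (n < 2L) stop("guide must have length >= 2", call. = FALSE)
  b <- strsplit(guide, "", fixed = TRUE)[[1L]]
  dinucs <- paste0(b[-n], b[-1L])
  out <- unname(params$stack[dinucs])
  names(out) <- paste0("dG_", seq_len(n - 1L))
  out
}

#' Total free energy of the fully paired guide-target duplex
#'
#' Sum of the nearest-neighbor stacks along the guide paired with its exact
#' complement, optionally plus the helix initiation penalty and a terminal
#' A.U penalty for each duplex end closed by an A.U (or U.A) pair. This is
#' the scalar duplex-stability feature dG; more negative = more stable.
#'
#' @param guide RNA string; default expectation is a 22-nt guide.
#' @param params an [nn_params()] set.
#' @param corrections logical; include initiation + terminal A.U penalties
#'   (default TRUE). With FALSE the value is the bare stack sum.
#' @param expected_length guide length to enforce; set `NULL` to accept any
#'   length >= 2 (library reuse).
#' @return free energy in kcal/mol.
#' @examples
#' duplex_dG_total(strrep("U", 22))
#' @export
duplex_dG_total <- function(guide, params = nn_params(), corrections = TRUE,
                            expected_length = 22L) {
  rna_check(guide, "guide")
  if (!is.null(expected_length) && nchar(guide) != expected_length) {
    stop("guide length ", nchar(guide), " != expected ", expected_length,
         " (pass expected_length = NULL to override)", call. = FALSE)
  }
  prof <- duplex_dG_profile(guide, params)
  total <- sum(prof)
  if (corrections) {
    b <- strsplit(guide, "", fixed = TRUE)[[1L]]
    ends <- c(b[1L], b[length(b)])
    total <- total + params$init + params$term_au * sum(ends %in% c("A", "U"))
  }
  total
}

# Vectorized duplex features for many equal-length guides: bare stack sum,
# corrected total, and the first-stack energy. Used by the feature builder
# and the scanner where per-guide calls would dominate runtime.
duplex_features_bulk <- function(guides, params = nn_params(),
                                 corrections = TRUE) {
  m <- seq_to_matrix(guides)
  n <- ncol(m)
  din <- matrix(paste0(m[, -n, drop = FALSE], m[, -1L, drop = FALSE]),
                nrow = nrow(m))
  e <- matrix(params$stack[din], nrow = nrow(m))
  total <- rowSums(e)
  if (corrections) {
    au_ends <- (m[, 1L] %in% c("A", "U")) + (m[, n] %in% c("A", "U"))
    total <- total + params$init + params$term_au * au_ends
  }
  list(dG = total, dG1 = e[, 1L], profile = e)
}
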