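#' @keywords internal
"_PACKAGE"

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and transcribes T to U. This is the only place DNA input is
#' accepted; every internal routine works strictly over ACGU.
#'
#' @param x character vector of sequences.
#' @param allow_other keep non-ACGU characters (e.g. N) instead of erroring.
#'   Callers that can skip ambiguous windows use this.
#' @return character vector over ACGU (plus other IUPAC codes if allowed).
#' @export
rna_normalize <- function(x, allow_other = FALSE) {
  x <- chartr("t", "u", tolower(x))
  x <- toupper(x)
  x <- chartr("T", "U", x)
  if (!allow_other) {
    bad <- grepl("[^ACGU]", x)
    if (any(bad)) {
      stop("non-RNA characters in sequence(s): ",
           paste(unique(gsub("[ACGU]", "", x[bad])), collapse = ""),
           call. = FALSE)
    }
  }
  x
}

rna_check <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  if (grepl("[^ACGU]", x)) {
    stop(what, " contains non-ACGU characters; call rna_normalize() first",
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of an RNA string
#' @param x RNA string (ACGU).
#' @return reverse complement, 5'->3'.
#' @export
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGU", "UGCA", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Split sequences into a character matrix of single bases
#' @param x character vector of equal-length sequences.
#' @return matrix, one row per sequence, one column per position.
#' @keywords internal
seq_to_matrix <- function(x) {
  n <- nchar(x)
  if (length(unique(n)) != 1L) stop("sequences must be the same length")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = n[1L], byrow = TRUE)
}

is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G")
}

# Run expressions under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
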