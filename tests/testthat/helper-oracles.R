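# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive: exhaustive enumeration and pair counting, never the
# dynamic programs they are checking.

# All nested Watson-Crick structures (dot-bracket) of a short sequence,
# minimum hairpin loop 3. Exponential; for length <= 14 only.
enumerate_structures <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(b)
  wc <- function(x, y) {
    (x == "A" && y == "U") || (x == "U" && y == "A") ||
    (x == "G" && y == "C") || (x == "C" && y == "G")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return("")
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- paste0(".", rec(i + 1L, j))          # i unpaired
    if (j - i >= 4L) {
      for (k in (i + 4L):j) {
        if (!wc(b[i], b[k])) next
        inner <- rec(i + 1L, k - 1L)
        after <- rec(k + 1L, j)
        out <- c(out, as.vector(outer(inner, after, function(x, y)
          paste0("(", x, ")", y))))
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# Brute-force MFE: minimum of structure_energy over every valid structure.
mfe_oracle <- function(seq, params = nn_params()) {
  structs <- enumerate_structures(seq)
  min(0, vapply(structs, function(s) structure_energy(seq, s, params),
                numeric(1)))
}

# AUC by Mann-Whitney pair counting (ties count 1/2).
auc_oracle <- function(predictions, labels) {
  pos <- predictions[labels]
  neg <- predictions[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Best ungapped antiparallel hybridization of two strands by exhaustive
# search over all start pairs and run lengths.
dimer_ungapped_oracle <- function(seqA, seqB, params = nn_params()) {
  a <- strsplit(seqA, "", fixed = TRUE)[[1L]]
  bb <- strsplit(seqB, "", fixed = TRUE)[[1L]]
  wc <- function(x, y) {
    (x == "A" && y == "U") || (x == "U" && y == "A") ||
    (x == "G" && y == "C") || (x == "C" && y == "G")
  }
  term <- function(x) if (x %in% c("A", "U")) params$term_au else 0
  best <- Inf
  for (i in seq_along(a)) {
    for (j in seq_along(bb)) {
      if (!wc(a[i], bb[j])) next
      lmax <- min(length(a) - i, j - 1L)
      e_st <- 0
      for (L in 0:lmax) {            # run of L+1 pairs starting at (i, j)
        if (L > 0L) {
          if (!wc(a[i + L], bb[j - L])) break
          e_st <- e_st + params$stack[[paste0(a[i + L - 1L], a[i + L])]]
        }
        e <- params$init + e_st + term(a[i]) + term(a[i + L])
        best <- min(best, e)
      }
    }
  }
  min(0, best)
}

# Deterministic guide passing every default filter (checked in tests).
clean_guide <- function() "CUCGGUAAUUGUCUUGAGUACA"
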