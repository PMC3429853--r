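#' Inter-molecular dimer free energy of two RNA strands
#'
#' Minimum free energy over all inter-molecular hybridizations of `seqA`
#' (5'->3') with `seqB` (antiparallel), allowing bulges and internal loops
#' between paired segments but no intramolecular pairs. The total is the
#' duplex initiation penalty plus stack and loop terms plus a terminal A.U
#' penalty at each helix end; 0 is returned when no hybridization is
#' stabilizing. With `seqA == seqB` this is the guide self-dimer energy.
#'
#' The stack table's reverse-complement symmetry makes the operation
#' symmetric in its two arguments.
#'
#' @param seqA,seqB RNA strings (ACGU).
#' @param params an [nn_params()] set.
#' @param maxloop largest total unpaired size bridged between two pairs.
#' @return free energy in kcal/mol, <= 0.
#' @examples
#' dimer_dG("ACGUACGU", "ACGUACGU")
#' @export
dimer_dG <- function(seqA, seqB, params = nn_params(), maxloop = 30L) {
  rna_check(seqA, "seqA")
  rna_check(seqB, "seqB")
  a <- strsplit(seqA, "", fixed = TRUE)[[1L]]
  bb <- strsplit(seqB, "", fixed = TRUE)[[1L]]
  na <- length(a); nb <- length(bb)
  can <- outer(a, bb, is_wc_pair)
  if (!any(can)) return(0)
  term_pen <- function(i, j) {
    if (a[i] %in% c("A", "U")) params$term_au else 0
  }
  lp_bulge <- vapply(seq_len(maxloop),
                     function(s) loop_penalty(params, "bulge", s), numeric(1))
  lp_internal <- c(NA_real_,
                   vapply(2:max(2L, maxloop),
                          function(s) loop_penalty(params, "internal", s),
                          numeric(1)))
  # H[i, j]: best chain of pairs ending with A[i].B[j], including the
  # 5'-terminal A.U penalty of its first pair. A indices ascend while B
  # indices descend (antiparallel duplex).
  H <- matrix(Inf, na, nb)
  best <- Inf
  for (i in seq_len(na)) {
    for (j in rev(seq_len(nb))) {
      if (!can[i, j]) next
      e <- term_pen(i, j)
      pmin_ <- max(1L, i - 1L - maxloop)
      if (i > 1L && j < nb) {
        for (p in (i - 1L):pmin_) {
          gap_a <- i - p - 1L
          qmax <- min(nb, j + 1L + (maxloop - gap_a))
          for (q in (j + 1L):qmax) {
            if (!is.finite(H[p, q])) next
            gap_b <- q - j - 1L
            link <- if (gap_a == 0L && gap_b == 0L) {
              unname(params$stack[paste0(a[p], a[i])])
            } else if (gap_a == 0L || gap_b == 0L) {
              lp_bulge[gap_a + gap_b]
            } else {
              lp_internal[gap_a + gap_b]
            }
            e <- min(e, H[p, q] + link)
          }
        }
      }
      H[i, j] <- e
      best <- min(best, e + term_pen(i, j))
    }
  }
  min(0, best + params$init)
}

#' Local secondary-structure free energy around a target site
#'
#' Extracts the window `[site_start - flank, site_start + site_length - 1 +
#' flank]` from the transcript (clipped to its bounds) and folds it with
#' [fold_self_dG()]. The MFE is a proxy for how structured, and hence how
#' occluded, the local target region is: more negative = more structured.
#'
#' @param transcript RNA string.
#' @param site_start 1-based start of the 22-nt target site.
#' @param window_flank nucleotides added on each side (default 100; the
#'   folding cost grows steeply with window size, so small flanks are
#'   recommended for bulk use).
#' @param params an [nn_params()] set.
#' @param site_length length of the target site (default 22).
#' @param maxloop passed to [fold_self_dG()].
#' @return free energy in kcal/mol, <= 0.
#' @export
target_local_dG <- function(transcript, site_start, window_flank = 100L,
                            params = nn_params(), site_length = 22L,
                            maxloop = 30L) {
  rna_check(transcript, "transcript")
  n <- nchar(transcript)
  if (site_start < 1L || site_start + site_length - 1L > n) {
    stop("site [", site_start, ", ", site_start + site_length - 1L,
         "] out of transcript bounds 1..", n, call. = FALSE)
  }
  from <- max(1L, site_start - window_flank)
  to <- min(n, site_start + site_length - 1L + window_flank)
  fold_self_dG(substr(transcript, from, to), params, maxloop)$mfe_dG
}
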