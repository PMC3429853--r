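#' Minimum-free-energy secondary structure of a short RNA
#'
#' Dynamic-programming MFE folding over nested (pseudoknot-free) structures,
#' intended for oligonucleotide-scale inputs (guides and local target
#' windows). The grammar is deliberately compact and fully checkable against
#' exhaustive enumeration: Watson-Crick pairs only, nearest-neighbor stack
#' energies, hairpin/bulge/internal loop penalties by total unpaired size
#' (minimum hairpin loop 3), a linear multiloop model
#' `ml_init + ml_branch * (branches + 1)`, no coaxial stacking, no dangles,
#' no terminal A.U penalty inside folds. An unstructured sequence scores 0
#' and the reported MFE is never positive: if every structure is
#' destabilizing the open chain wins.
#'
#' @param seq RNA string (ACGU), any length >= 1 (intended <= a few hundred
#'   nt; cost grows as length^2 * maxloop^2).
#' @param params an [nn_params()] set.
#' @param maxloop largest total unpaired size considered for a bulge or
#'   internal loop (default 30).
#' @return object of class `fold_result`: list with `mfe_dG` (kcal/mol,
#'   <= 0) and `structure` (dot-bracket string of the same length).
#' @examples
#' fold_self_dG("GGGGAAAACCCC")
#' @export
fold_self_dG <- function(seq, params = nn_params(), maxloop = 30L) {
  rna_check(seq, "seq")
  n <- nchar(seq)
  open <- structure(list(mfe_dG = 0, structure = strrep(".", n)),
                    class = "fold_result")
  if (n < 5L) return(open)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]

  canpair <- outer(b, b, is_wc_pair)
  stack_of <- unname(params$stack[paste0(b[-n], b[-1L])])  # stack closing (i,j)->(i+1,j-1)
  hp <- vapply(3:(n - 2L), function(s) loop_penalty(params, "hairpin", s),
               numeric(1))
  hp_pen <- function(s) hp[s - 2L]
  lp_bulge <- vapply(seq_len(maxloop),
                     function(s) loop_penalty(params, "bulge", s), numeric(1))
  lp_internal <- c(NA_real_,
                   vapply(2:max(2L, maxloop),
                          function(s) loop_penalty(params, "internal", s),
                          numeric(1)))
  mlb <- params$ml_branch

  V <- matrix(Inf, n, n)
  WM <- matrix(Inf, n, n)
  WM2 <- matrix(Inf, n, n)

  for (span in 4:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      # --- V(i, j): best structure closed by pair (i, j)
      if (canpair[i, j]) {
        best <- hp_pen(j - i - 1L)
        # interior: inner pair (k, l); needs k >= i+1, l <= j-1, l >= k+4
        kmax <- min(i + 1L + maxloop, j - 5L)
        if (j - i >= 6L) for (k in (i + 1L):kmax) {
          left <- k - i - 1L
          lmin <- max(k + 4L, j - 1L - (maxloop - left))
          if (lmin > j - 1L) next
          ls <- lmin:(j - 1L)
          vin <- V[k, ls]
          fin <- which(is.finite(vin))
          if (!length(fin)) next
          ls <- ls[fin]; vin <- vin[fin]
          right <- j - ls - 1L
          tot <- left + right
          le <- numeric(length(ls))
          sel <- tot == 0L
          if (any(sel)) le[sel] <- stack_of[i]
          sel <- tot > 0L & (left == 0L | right == 0L)
          if (any(sel)) le[sel] <- lp_bulge[tot[sel]]
          sel <- left > 0L & right > 0L
          if (any(sel)) le[sel] <- lp_internal[tot[sel]]
          best <- min(best, min(vin + le))
        }
        # multiloop with >= 2 inner branches
        if (j - i >= 6L) {
          m <- WM2[i + 1L, j - 1L]
          if (is.finite(m)) best <- min(best, params$ml_init + mlb + m)
        }
        V[i, j] <- best
      }
      # --- WM(i, j): >= 1 branch in [i, j], +ml_branch per branch
      w <- min(WM[i + 1L, j], WM[i, j - 1L], V[i, j] + mlb)
      ks <- (i + 1L):j
      cand <- WM[i, ks - 1L] + V[ks, j] + mlb
      w <- min(w, suppressWarnings(min(cand)))
      WM[i, j] <- w
      # --- WM2(i, j): >= 2 branches
      w2 <- min(WM2[i, j - 1L], suppressWarnings(min(cand)))
      WM2[i, j] <- w2
    }
  }

  W <- c(0, rep(0, n))  # W[j + 1] = best energy of prefix 1..j
  for (j in seq_len(n)) {
    w <- W[j]
    ks <- seq_len(j)
    vv <- V[cbind(ks, j)]
    fin <- which(is.finite(vv))
    if (length(fin)) w <- min(w, min(W[ks[fin]] + vv[fin]))
    W[j + 1L] <- w
  }
  if (W[n + 1L] >= 0) return(open)

  pairs <- fold_traceback(n, V, WM, WM2, W, canpair, stack_of, hp_pen,
                          lp_bulge, lp_internal, params, maxloop)
  db <- rep(".", n)
  db[pairs[, 1L]] <- "("
  db[pairs[, 2L]] <- ")"
  structure(list(mfe_dG = W[n + 1L], structure = paste(db, collapse = "")),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, "\n", sprintf("MFE = %.2f kcal/mol", x$mfe_dG), "\n",
      sep = "")
  invisible(x)
}

# Recursive traceback re-deriving the argmins of the fill phase.
fold_traceback <- function(n, V, WM, WM2, W, canpair, stack_of, hp_pen,
                           lp_bulge, lp_internal, params, maxloop) {
  pairs <- list()
  eps <- 1e-9
  mlb <- params$ml_branch

  tb_V <- function(i, j) {
    pairs[[length(pairs) + 1L]] <<- c(i, j)
    e <- V[i, j]
    if (abs(e - hp_pen(j - i - 1L)) < eps) return(invisible())
    kmax <- min(i + 1L + maxloop, j - 5L)
    if (j - i >= 6L) for (k in (i + 1L):kmax) {
      left <- k - i - 1L
      lmin <- max(k + 4L, j - 1L - (maxloop - left))
      if (lmin > j - 1L) next
      for (l in (j - 1L):lmin) {
        if (!is.finite(V[k, l])) next
        right <- j - l - 1L
        tot <- left + right
        le <- if (tot == 0L) stack_of[i]
              else if (left == 0L || right == 0L) lp_bulge[tot]
              else lp_internal[tot]
        if (abs(e - (V[k, l] + le)) < eps) {
          tb_V(k, l)
          return(invisible())
        }
      }
    }
    if (j - i >= 6L && is.finite(WM2[i + 1L, j - 1L]) &&
        abs(e - (params$ml_init + mlb + WM2[i + 1L, j - 1L])) < eps) {
      tb_WM2(i + 1L, j - 1L)
      return(invisible())
    }
    stop("traceback failure in V at (", i, ",", j, ")")
  }
  tb_WM <- function(i, j) {
    e <- WM[i, j]
    if (is.finite(WM[i + 1L, j]) && abs(e - WM[i + 1L, j]) < eps) {
      return(tb_WM(i + 1L, j))
    }
    if (is.finite(WM[i, j - 1L]) && abs(e - WM[i, j - 1L]) < eps) {
      return(tb_WM(i, j - 1L))
    }
    if (is.finite(V[i, j]) && abs(e - (V[i, j] + mlb)) < eps) {
      return(tb_V(i, j))
    }
    for (k in (i + 1L):j) {
      if (is.finite(WM[i, k - 1L]) && is.finite(V[k, j]) &&
          abs(e - (WM[i, k - 1L] + V[k, j] + mlb)) < eps) {
        tb_WM(i, k - 1L)
        tb_V(k, j)
        return(invisible())
      }
    }
    stop("traceback failure in WM at (", i, ",", j, ")")
  }
  tb_WM2 <- function(i, j) {
    e <- WM2[i, j]
    if (is.finite(WM2[i, j - 1L]) && abs(e - WM2[i, j - 1L]) < eps) {
      return(tb_WM2(i, j - 1L))
    }
    for (k in (i + 1L):j) {
      if (is.finite(WM[i, k - 1L]) && is.finite(V[k, j]) &&
          abs(e - (WM[i, k - 1L] + V[k, j] + mlb)) < eps) {
        tb_WM(i, k - 1L)
        tb_V(k, j)
        return(invisible())
      }
    }
    stop("traceback failure in WM2 at (", i, ",", j, ")")
  }
  tb_W <- function(j) {
    while (j >= 1L) {
      if (abs(W[j + 1L] - W[j]) < eps) {
        j <- j - 1L
        next
      }
      for (k in seq_len(j)) {
        if (is.finite(V[k, j]) && abs(W[j + 1L] - (W[k] + V[k, j])) < eps) {
          tb_V(k, j)
          j <- k - 1L
          break
        }
      }
    }
  }
  tb_W(n)
  do.call(rbind, pairs)
}

#' Free energy of a given dot-bracket structure
#'
#' Scores an explicit nested structure under exactly the same energy model
#' as [fold_self_dG()]: stacks for adjacent pairs, hairpin/bulge/internal
#' penalties by total unpaired size, `ml_init + ml_branch * (branches + 1)`
#' for multiloops, nothing for external bases. Used as the shared scorer by
#' the enumeration oracle in the test-suite; for any sequence the minimum of
#' this function over all valid structures equals the folder's MFE.
#'
#' @param seq RNA string.
#' @param structure dot-bracket string of the same length (no pseudoknots).
#' @param params an [nn_params()] set.
#' @return free energy in kcal/mol (0 for the all-dot structure).
#' @export
structure_energy <- function(seq, structure, params = nn_params()) {
  rna_check(seq, "seq")
  if (nchar(structure) != nchar(seq)) {
    stop("structure and sequence lengths differ", call. = FALSE)
  }
  db <- strsplit(structure, "", fixed = TRUE)[[1L]]
  st <- integer(0)
  pair_of <- integer(length(db))
  for (x in seq_along(db)) {
    if (db[x] == "(") st <- c(st, x)
    else if (db[x] == ")") {
      if (!length(st)) stop("unbalanced structure", call. = FALSE)
      i <- st[length(st)]
      st <- st[-length(st)]
      pair_of[i] <- x
      pair_of[x] <- i
    } else if (db[x] != ".") stop("bad structure character", call. = FALSE)
  }
  if (length(st)) stop("unbalanced structure", call. = FALSE)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  opens <- which(db == "(")
  if (!length(opens)) return(0)
  for (i in opens) {
    if (!is_wc_pair(b[i], b[pair_of[i]])) {
      stop("non-Watson-Crick pair at (", i, ",", pair_of[i], ")",
           call. = FALSE)
    }
  }
  e <- 0
  for (i in opens) {
    j <- pair_of[i]
    # children = pairs directly nested under (i, j)
    kids <- list()
    x <- i + 1L
    unpaired <- 0L
    while (x < j) {
      if (pair_of[x] > 0L) {
        kids[[length(kids) + 1L]] <- c(x, pair_of[x])
        x <- pair_of[x] + 1L
      } else {
        unpaired <- unpaired + 1L
        x <- x + 1L
      }
    }
    if (length(kids) == 0L) {
      if (unpaired < 3L) stop("hairpin loop < 3 nt", call. = FALSE)
      e <- e + loop_penalty(params, "hairpin", unpaired)
    } else if (length(kids) == 1L) {
      k <- kids[[1L]][1L]; l <- kids[[1L]][2L]
      left <- k - i - 1L; right <- j - l - 1L
      if (left == 0L && right == 0L) {
        e <- e + unname(params$stack[paste0(b[i], b[k])])
      } else if (left == 0L || right == 0L) {
        e <- e + loop_penalty(params, "bulge", left + right)
      } else {
        e <- e + loop_penalty(params, "internal", left + right)
      }
    } else {
      e <- e + params$ml_init + params$ml_branch * (length(kids) + 1L)
    }
  }
  e
}
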