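#' Load a coefficient model
#'
#' A coefficient table is an intercept plus named term weights resolvable
#' against feature-vector columns (`A_1` ... `U_22`, `dG`, `dG2`, `dG3`,
#' `dG1`, ...). The built-in `"table2"` model is the published
#' multiple-regression model for the complete sensor-assay database:
#' 4 thermodynamic terms (a cubic in duplex dG plus the first-stack dG1)
#' and 37 position-dependent nucleotide terms, intercept -43.85, predicting
#' the natural log of the silencing score.
#'
#' @param model `"table2"` or a path to a JSON file of the same shape
#'   (`{"name": ..., "intercept": ..., "terms": {...}}`).
#' @return object of class `coef_table`.
#' @examples
#' m <- mirscan_model("table2")
#' m$intercept
#' @export
mirscan_model <- function(model = "table2") {
  if (inherits(model, "coef_table")) return(model)
  path <- if (identical(model, "table2")) {
    system.file("extdata", "table2.json", package = "mirscan", mustWork = TRUE)
  } else model
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$intercept) || is.null(j$terms)) {
    stop("invalid model JSON (need 'intercept' and 'terms'): ", path,
         call. = FALSE)
  }
  coef_table(j$intercept, unlist(j$terms),
             name = if (!is.null(j$name)) j$name else basename(path),
             source = j$source)
}

#' Construct a coefficient table
#' @param intercept numeric intercept.
#' @param terms named numeric vector of term weights.
#' @param name,source metadata strings.
#' @return object of class `coef_table`.
#' @export
coef_table <- function(intercept, terms, name = "custom", source = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(terms), !is.null(names(terms)), all(nzchar(names(terms))))
  structure(list(name = name, source = source,
                 intercept = unname(intercept), terms = terms),
            class = "coef_table")
}

#' @export
print.coef_table <- function(x, ...) {
  cat("<coef_table> ", x$name, ": intercept ", x$intercept, " + ",
      length(x$terms), " terms\n", sep = "")
  invisible(x)
}

#' Write a coefficient table to JSON
#' @param coeffs a `coef_table`.
#' @param path output file.
#' @export
write_model <- function(coeffs, path) {
  jsonlite::write_json(
    list(name = coeffs$name, source = coeffs$source,
         intercept = coeffs$intercept, terms = as.list(coeffs$terms)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Score feature vectors with a coefficient model
#'
#' Linear predictor `intercept + sum(weight * feature)` on the ln
#' silencing-score scale. Every model term must resolve to a feature
#' column; a thermodynamics-requiring model applied to an indicators-only
#' feature vector is a configuration error, not a silent zero.
#'
#' @param fv named feature vector, or a feature matrix with named columns
#'   (one row per candidate).
#' @param coeffs a `coef_table` (or anything [mirscan_model()] accepts).
#' @return numeric predicted ln silencing score (vector for a matrix input).
#' @examples
#' fv <- build_feature_vector("UAAAAGGCAUCUUUCAUCUAGC")
#' score(fv, mirscan_model("table2"))
#' @export
score <- function(fv, coeffs = mirscan_model("table2")) {
  coeffs <- mirscan_model(coeffs)
  tn <- names(coeffs$terms)
  if (is.null(dim(fv))) {
    missing <- setdiff(tn, names(fv))
    if (length(missing)) {
      stop("feature vector lacks model term(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(coeffs$intercept + sum(coeffs$terms * fv[tn]))
  }
  missing <- setdiff(tn, colnames(fv))
  if (length(missing)) {
    stop("feature matrix lacks model term(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  drop(coeffs$intercept + fv[, tn, drop = FALSE] %*% coeffs$terms)
}

#' Read / write guide activity tables
#'
#' Tab-separated tables with columns `guide_seq` (22-nt guide, 5'->3'; T is
#' transcribed to U on read) and `silencing_percent` in \[0, 100\], plus
#' optional `source`, `ln_activity` (latent ln-scale response, written by
#' the synthetic generator) and `clipped`.
#'
#' @param path file path.
#' @return data.frame of activity records.
#' @export
read_activity_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = NA, stringsAsFactors = FALSE)
  if (!all(c("guide_seq", "silencing_percent") %in% names(d))) {
    stop("activity table needs columns guide_seq, silencing_percent: ",
         path, call. = FALSE)
  }
  d$guide_seq <- rna_normalize(d$guide_seq)
  if (any(d$silencing_percent < 0 | d$silencing_percent > 100)) {
    stop("silencing_percent outside [0, 100] in ", path, call. = FALSE)
  }
  d
}

#' @rdname read_activity_table
#' @param dataset data.frame of activity records.
#' @export
write_activity_table <- function(dataset, path) {
  utils::write.table(dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' ln-scale response of an activity table
#'
#' Returns the regression response: the `ln_activity` column when present
#' (the synthetic generator stores the latent ln-scale value there,
#' untouched by percent-scale clipping), otherwise the natural log of
#' `silencing_percent` floored at `ln_floor` percent. The floor guards
#' ln(0); records at 0 are treated as `ln_floor`% silencing.
#'
#' @param dataset activity data.frame.
#' @param ln_floor floor in percent (default 0.5).
#' @param use_latent use the `ln_activity` column when present.
#' @return numeric response vector.
#' @export
activity_response <- function(dataset, ln_floor = 0.5, use_latent = TRUE) {
  if (use_latent && "ln_activity" %in% names(dataset)) {
    return(dataset$ln_activity)
  }
  log(pmax(dataset$silencing_percent, ln_floor))
}

#' Pearson correlation of feature columns with the response
#'
#' @param X feature matrix with named columns.
#' @param y response; raw percent activity when `ln = TRUE` (then floored
#'   and logged), already on the modelling scale when `ln = FALSE`.
#' @param ln take ln of `y` first.
#' @param ln_floor floor used with `ln = TRUE`.
#' @return data.frame-like list with `R`, `p` (two-sided), `degenerate`
#'   (constant columns: R reported as 0, p as 1), each named by column.
#' @export
correlate_features <- function(X, y, ln = FALSE, ln_floor = 0.5) {
  if (ln) y <- log(pmax(y, ln_floor))
  n <- length(y)
  if (n < 3L) stop("need >= 3 records", call. = FALSE)
  if (stats::sd(y) == 0) {
    k <- ncol(X)
    return(list(R = stats::setNames(rep(0, k), colnames(X)),
                p = stats::setNames(rep(1, k), colnames(X)),
                degenerate = stats::setNames(rep(TRUE, k), colnames(X))))
  }
  sds <- apply(X, 2L, stats::sd)
  degen <- sds == 0
  R <- rep(0, ncol(X))
  names(R) <- colnames(X)
  if (any(!degen)) {
    R[!degen] <- drop(stats::cor(X[, !degen, drop = FALSE], y))
  }
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[degen] <- 1
  names(p) <- colnames(X)
  list(R = R, p = p, degenerate = stats::setNames(degen, colnames(X)))
}

#' Correlation screening with split-stability
#'
#' Selects features whose correlation with ln activity is (i) at least
#' `r_min` in magnitude, (ii) significant at `p_max`, and (iii) stable
#' across data subsets: the dataset is split at random into `n_splits`
#' equal parts, the per-part correlation is computed for every feature,
#' and over `n_repeats` such splits the standard deviation of R (the S_n
#' stability value) must not exceed `s_max`.
#'
#' @param dataset activity data.frame.
#' @param X feature matrix (default: indicators + thermodynamic terms).
#' @param r_min minimum |R| (default 0.014).
#' @param p_max significance level (default 0.05).
#' @param n_splits parts per split, 5 or 10 (default 5).
#' @param n_repeats random splits (default 1000).
#' @param s_max S_n cut-off (default 0.065).
#' @param seed RNG seed for the splits.
#' @param ln_floor percent floor before ln.
#' @return object of class `selection_report`: data.frame with columns
#'   `feature`, `R`, `p`, `S_n`, `kept`.
#' @export
select_parameters <- function(dataset, X = NULL, r_min = 0.014, p_max = 0.05,
                              n_splits = 5L, n_repeats = 1000L,
                              s_max = 0.065, seed = NULL, ln_floor = 0.5) {
  y <- activity_response(dataset, ln_floor)
  if (is.null(X)) X <- feature_matrix(dataset$guide_seq)
  n <- length(y)
  if (n < 3L * n_splits) {
    stop("dataset too small: each of the ", n_splits,
         " parts needs >= 3 records", call. = FALSE)
  }
  full <- correlate_features(X, y)
  part_R <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_repeats * n_splits, ncol = ncol(X))
    row <- 1L
    for (rep_i in seq_len(n_repeats)) {
      part <- sample(rep(seq_len(n_splits), length.out = n))
      for (s in seq_len(n_splits)) {
        idx <- which(part == s)
        out[row, ] <- suppressWarnings(
          drop(stats::cor(X[idx, , drop = FALSE], y[idx])))
        row <- row + 1L
      }
    }
    out
  })
  S_n <- apply(part_R, 2L, stats::sd, na.rm = TRUE)
  kept <- abs(full$R) >= r_min & full$p < p_max & S_n <= s_max &
    !full$degenerate
  structure(data.frame(feature = colnames(X), R = unname(full$R),
                       p = unname(full$p), S_n = unname(S_n),
                       kept = unname(kept), row.names = NULL),
            class = c("selection_report", "data.frame"),
            n_splits = n_splits, n_repeats = n_repeats,
            thresholds = c(r_min = r_min, p_max = p_max, s_max = s_max))
}

#' Ordinary least squares fit with classical inference
#'
#' Fits `ln activity ~ features` by QR least squares and reports classical
#' t-test p-values per coefficient, the residual sigma, and the training
#' Pearson correlation between fitted and observed response. Rank
#' deficiency is a hard error naming the collinear columns.
#'
#' @param dataset activity data.frame.
#' @param columns character vector of feature columns to use (default: all
#'   columns of `X`).
#' @param X feature matrix (default: indicators + thermo terms for the
#'   guides in `dataset`).
#' @param ln_floor percent floor before ln.
#' @return object of class `model_fit`: list with `coeffs` (a
#'   `coef_table`), `pvalues` (named, intercept included as
#'   `(Intercept)`), `se`, `sigma`, `df_residual`, `training_R`,
#'   `fitted`, `columns`.
#' @export
fit_ols <- function(dataset, columns = NULL, X = NULL, ln_floor = 0.5) {
  y <- activity_response(dataset, ln_floor)
  if (is.null(X)) X <- feature_matrix(dataset$guide_seq)
  if (!is.null(columns)) {
    missing <- setdiff(columns, colnames(X))
    if (length(missing)) {
      stop("unknown feature column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    X <- X[, columns, drop = FALSE]
  }
  M <- cbind(`(Intercept)` = 1, X)
  if (nrow(M) <= ncol(M)) {
    stop("need more rows (", nrow(M), ") than columns (", ncol(M), ")",
         call. = FALSE)
  }
  qr_ <- qr(M)
  if (qr_$rank < ncol(M)) {
    bad <- colnames(M)[qr_$pivot[(qr_$rank + 1L):ncol(M)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_, y)
  fitted <- drop(M %*% beta)
  res <- y - fitted
  df <- nrow(M) - ncol(M)
  sigma2 <- sum(res^2) / df
  d_piv <- diag(chol2inv(qr.R(qr_)))  # pivoted column order
  d <- numeric(ncol(M))
  d[qr_$pivot] <- d_piv
  se <- sqrt(pmax(d, 0) * sigma2)
  names(se) <- colnames(M)
  tstat <- beta / se
  pvals <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  structure(list(
    coeffs = coef_table(beta[1L], beta[-1L], name = "ols_fit"),
    pvalues = pvals, se = se, sigma = sqrt(sigma2), df_residual = df,
    training_R = if (stats::sd(fitted) > 0) stats::cor(fitted, y) else 0,
    fitted = fitted, columns = colnames(X)
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", length(x$coeffs$terms), " terms, training R = ",
      round(x$training_R, 4), ", sigma = ", round(x$sigma, 4), "\n", sep = "")
  invisible(x)
}

#' Iterative reduction of an OLS model
#'
#' Refits repeatedly, removing insignificant terms (p >= `p_max`) under
#' the published protocol: per round, at most one nucleotide indicator per
#' sequence position may be removed (the one with the largest p-value at
#' that position), and at most one thermodynamic (non-indicator) term (the
#' largest p overall). Stops when every remaining term is significant or
#' nothing is removable.
#'
#' @param dataset activity data.frame.
#' @param columns starting feature columns.
#' @param X feature matrix.
#' @param p_max significance threshold (default 0.05).
#' @param ln_floor percent floor before ln.
#' @return final `model_fit`, with attribute `rounds` (number of refits)
#'   and `removed` (columns removed, in order).
#' @export
reduce_model <- function(dataset, columns = NULL, X = NULL, p_max = 0.05,
                         ln_floor = 0.5) {
  if (is.null(X)) X <- feature_matrix(dataset$guide_seq)
  if (is.null(columns)) columns <- colnames(X)
  removed <- character(0)
  rounds <- 0L
  repeat {
    fit <- fit_ols(dataset, columns, X, ln_floor)
    rounds <- rounds + 1L
    pv <- fit$pvalues[setdiff(names(fit$pvalues), "(Intercept)")]
    insig <- pv[pv >= p_max]
    if (!length(insig)) break
    is_nuc <- grepl("^[ACGU]_[0-9]+$", names(insig))
    drop_now <- character(0)
    if (any(is_nuc)) {
      nuc <- insig[is_nuc]
      pos <- sub("^[ACGU]_", "", names(nuc))
      for (p in unique(pos)) {
        at_p <- nuc[pos == p]
        drop_now <- c(drop_now, names(at_p)[which.max(at_p)])
      }
    }
    if (any(!is_nuc)) {
      th <- insig[!is_nuc]
      drop_now <- c(drop_now, names(th)[which.max(th)])
    }
    if (!length(drop_now)) break
    removed <- c(removed, drop_now)
    columns <- setdiff(columns, drop_now)
    if (!length(columns)) break
  }
  attr(fit, "rounds") <- rounds
  attr(fit, "removed") <- removed
  fit
}

#' Non-overlapping n-fold cross-validation
#'
#' Splits the records into `n` disjoint, equal-sized (within one) folds,
#' trains on each complement and predicts the held-out fold, so every
#' record is predicted exactly once. Reports the coefficient of
#' determination computed as
#' `R2 = (ActualVariation - Error) / ActualVariation` with
#' `ActualVariation = sum((y - mean(y))^2)` and
#' `Error = sum((y - yhat)^2)`, plus the Pearson correlation between
#' out-of-fold predictions and the response. For non-cross-validated
#' predictions this R2 definition coincides exactly with the squared
#' Pearson correlation.
#'
#' @param dataset activity data.frame.
#' @param n number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param columns feature columns for the default OLS pipeline.
#' @param X feature matrix.
#' @param pipeline optional function `(train_dataset, train_X) ->` object
#'   with `$coeffs` (e.g. [fit_ols()] or [reduce_model()] wrapped); run
#'   independently inside every training fold.
#' @param ln_floor percent floor before ln.
#' @return object of class `cv_result`: list with `predictions` (length n
#'   records, out-of-fold), `fold` assignment, `R2`, `R`.
#' @export
cross_validate <- function(dataset, n = 5L, seed = NULL, columns = NULL,
                           X = NULL, pipeline = NULL, ln_floor = 0.5) {
  N <- nrow(dataset)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (n > N) stop("more folds than records", call. = FALSE)
  if (is.null(X)) X <- feature_matrix(dataset$guide_seq)
  y <- activity_response(dataset, ln_floor)
  fold <- with_seed(seed, sample(rep(seq_len(n), length.out = N)))
  preds <- numeric(N)
  for (f in seq_len(n)) {
    tr <- fold != f
    fitobj <- if (is.null(pipeline)) {
      fit_ols(dataset[tr, , drop = FALSE], columns, X[tr, , drop = FALSE],
              ln_floor)
    } else {
      pipeline(dataset[tr, , drop = FALSE], X[tr, , drop = FALSE])
    }
    preds[!tr] <- score(X[!tr, , drop = FALSE], fitobj$coeffs)
  }
  structure(list(predictions = preds, fold = fold,
                 R2 = r_squared(y, preds),
                 R = stats::cor(preds, y)),
            class = "cv_result")
}

#' Coefficient of determination by the actual-variation formula
#'
#' `R2 = (sum((y - mean(y))^2) - sum((y - yhat)^2)) / sum((y - mean(y))^2)`.
#' Can be negative for predictions worse than the mean; equals 0 for the
#' constant mean predictor and equals the squared Pearson correlation for
#' in-sample least-squares predictions.
#'
#' @param actual,predicted numeric vectors.
#' @return scalar R2.
#' @export
r_squared <- function(actual, predicted) {
  av <- sum((actual - mean(actual))^2)
  err <- sum((actual - predicted)^2)
  (av - err) / av
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", max(x$fold), " folds: R2 = ", round(x$R2, 4),
      ", Pearson R = ", round(x$R, 4), "\n", sep = "")
  invisible(x)
}

#' ROC analysis of continuous predictions against binary efficiency
#'
#' Labels records as efficient when their measured activity reaches
#' `efficiency_threshold` percent and sweeps all prediction thresholds.
#' AUC is computed by the trapezoidal rule, which (ties handled by the
#' trapezoid) equals the normalized Mann-Whitney U statistic.
#'
#' @param predictions numeric model scores.
#' @param activities measured silencing percent in \[0, 100\].
#' @param efficiency_threshold percent defining "efficient" (default 75).
#' @return object of class `roc_result`: list with `fpr`, `tpr`,
#'   `thresholds`, `auc`, `efficiency_threshold`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(predictions, activities, efficiency_threshold = 75) {
  stopifnot(length(predictions) == length(activities))
  labels <- activities >= efficiency_threshold
  if (all(labels) || !any(labels)) {
    stop("both classes must be present at threshold ",
         efficiency_threshold, "%", call. = FALSE)
  }
  ord <- order(predictions, decreasing = TRUE)
  lab <- labels[ord]
  pred <- predictions[ord]
  # collapse tied prediction values into single operating points
  keep <- c(diff(pred) != 0, TRUE)
  tp <- cumsum(lab)[keep]
  fp <- cumsum(!lab)[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, pred[keep]), auc = auc,
                 efficiency_threshold = efficiency_threshold,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", round(x$auc, 4), " (", x$n_pos, " efficient / ",
      x$n_neg, " inefficient at ", x$efficiency_threshold, "%)\n", sep = "")
  invisible(x)
}

#' Bin records by a feature and average activity per bin
#'
#' Categorizes records into right-closed intervals `(e_k, e_(k+1)]` over
#' the supplied edges (values exactly on an interior edge fall in the bin
#' to its left) and reports mean activity and count per bin; empty bins
#' are kept with count 0. Records at or below the first edge or above the
#' last are excluded and counted in the `n_excluded` attribute.
#'
#' @param values feature values (e.g. duplex dG), one per record.
#' @param activities activity values to average.
#' @param edges strictly increasing numeric bin edges.
#' @return data.frame with `bin_left`, `bin_right`, `mean_activity`, `n`.
#' @export
bin_by_feature <- function(values, activities, edges) {
  stopifnot(length(values) == length(activities))
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing",
                                  call. = FALSE)
  idx <- findInterval(values, edges, left.open = TRUE,
                      rightmost.closed = FALSE)
  # findInterval with left.open: value in (e_k, e_(k+1)] -> k
  inb <- idx >= 1L & idx <= length(edges) - 1L & values <= edges[length(edges)]
  k <- length(edges) - 1L
  mean_act <- rep(NA_real_, k)
  n <- integer(k)
  for (b in seq_len(k)) {
    sel <- inb & idx == b
    n[b] <- sum(sel)
    if (n[b] > 0L) mean_act[b] <- mean(activities[sel])
  }
  out <- data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1L],
                    mean_activity = mean_act, n = n)
  attr(out, "n_excluded") <- sum(!inb)
  out
}
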