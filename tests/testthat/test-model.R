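test_that("built-in model reproduces the published coefficient table", {
  m <- mirscan_model("table2")
  expect_s3_class(m, "coef_table")
  expect_identical(m$intercept, -43.85)
  expect_length(m$terms, 41L)  # 4 thermodynamic + 37 nucleotide terms
  expect_identical(m$terms[["dG"]], -2.694)
  expect_identical(m$terms[["dG2"]], -0.06917)
  expect_identical(m$terms[["dG3"]], -0.0005959)
  expect_identical(m$terms[["dG1"]], 0.3705)
  expect_identical(m$terms[["U_1"]], 1.989)
  expect_identical(m$terms[["A_20"]], -1.067)
  expect_length(grep("^[ACGU]_[0-9]+$", names(m$terms)), 37L)
})

test_that("scoring is the linear predictor, with exact indicator differences", {
  m <- mirscan_model("table2")
  zero <- setNames(numeric(92), c(names(one_hot(strrep("A", 22))),
                                  "dG", "dG2", "dG3", "dG1"))
  expect_equal(score(zero, m), -43.85)
  a20 <- zero; a20[["A_20"]] <- 1
  c20 <- zero; c20[["C_20"]] <- 1
  expect_equal(score(a20, m) - score(c20, m), -1.067)
  cubic <- zero
  cubic[["dG"]] <- -30; cubic[["dG2"]] <- 900; cubic[["dG3"]] <- -27000
  expect_equal(score(cubic, m),
               -43.85 + (-2.694) * (-30) + (-0.06917) * 900 +
                 (-0.0005959) * (-27000))
  # matrix scoring agrees with vector scoring
  guides <- synth_guides(10, seed = 601)
  X <- feature_matrix(guides)
  expect_equal(unname(score(X, m)),
               vapply(guides, function(g) score(build_feature_vector(g), m),
                      numeric(1), USE.NAMES = FALSE))
  expect_error(score(zero[1:10], m), "lacks model term")
})

test_that("correlation screening behaves at the trivial poles", {
  d <- synth_activity_dataset(300, seed = 602)
  y <- activity_response(d)
  X <- cbind(self = y, anti = -y, noise = mirscan:::with_seed(603, rnorm(300)),
             const = 1)
  r <- correlate_features(X, y)
  expect_equal(unname(r$R[c("self", "anti")]), c(1, -1))
  expect_lt(abs(r$R[["noise"]]), 0.2)
  expect_identical(unname(r$R[["const"]]), 0)
  expect_identical(unname(r$p[["const"]]), 1)
  expect_true(r$degenerate[["const"]])
  expect_error(correlate_features(X[1:2, ], y[1:2]), ">= 3")
})

test_that("select_parameters keeps planted signal, rejects noise, honours trivial thresholds", {
  d <- synth_activity_dataset(1000, seed = 604)
  y <- activity_response(d)
  X <- cbind(planted = y + mirscan:::with_seed(605, rnorm(1000, sd = 1.5)),
             noise = mirscan:::with_seed(606, rnorm(1000)))
  rep_ <- select_parameters(d, X, n_repeats = 200, seed = 607)
  expect_s3_class(rep_, "selection_report")
  expect_true(rep_$kept[rep_$feature == "planted"])
  expect_false(rep_$kept[rep_$feature == "noise"])
  all_kept <- select_parameters(d, X, r_min = 0, p_max = 1, s_max = Inf,
                                n_repeats = 50, seed = 608)
  expect_true(all(all_kept$kept))
  expect_error(select_parameters(d[1:10, ], X[1:10, ], n_repeats = 2),
               "too small")
})

test_that("fit_ols recovers a noiseless linear model exactly and flags collinearity", {
  x <- seq(-3, 3, length.out = 50)
  d <- data.frame(guide_seq = synth_guides(50, seed = 609),
                  silencing_percent = 50,
                  ln_activity = 2 * x + 1)
  X <- cbind(x = x)
  fit <- fit_ols(d, X = X)
  expect_equal(unname(fit$coeffs$terms[["x"]]), 2)
  expect_equal(fit$coeffs$intercept, 1)
  expect_equal(fit$training_R, 1)
  X2 <- cbind(x = x, x_copy = x)
  expect_error(fit_ols(d, X = X2), "rank deficient.*x_copy")
  expect_error(fit_ols(d[1:2, ], X = X[1:2, , drop = FALSE]), "more rows")
  expect_error(fit_ols(d, columns = "nope", X = X), "unknown feature")
})

test_that("non-CV R2 identity: formula equals squared Pearson R", {
  d <- synth_activity_dataset(400, seed = 610)
  X <- feature_matrix(d$guide_seq)
  cols <- names(mirscan_model("table2")$terms)
  fit <- fit_ols(d, columns = cols, X = X)
  y <- activity_response(d)
  expect_equal(r_squared(y, fit$fitted), cor(fit$fitted, y)^2,
               tolerance = 1e-12)
  # mean predictor scores exactly 0
  expect_equal(r_squared(y, rep(mean(y), length(y))), 0)
})

test_that("reduce_model removes insignificant terms under the one-per-position rule", {
  set.seed(611)
  n <- 800
  x1 <- rnorm(n); x2 <- rnorm(n)
  irr_a <- rbinom(n, 1, 0.5); irr_b <- rbinom(n, 1, 0.5)
  d <- data.frame(guide_seq = synth_guides(n),
                  silencing_percent = 50,
                  ln_activity = 1.5 * x1 - 2 * x2 + rnorm(n))
  X <- cbind(x1 = x1, x2 = x2, A_5 = irr_a, C_5 = irr_b)
  fit <- reduce_model(d, X = X)
  expect_setequal(fit$columns, c("x1", "x2"))
  # both irrelevant indicators sit at position 5: must go in separate rounds
  expect_gte(attr(fit, "rounds"), 3L)
  expect_setequal(attr(fit, "removed"), c("A_5", "C_5"))
  # all-significant model returns unchanged in one round
  fit2 <- reduce_model(d, X = X[, c("x1", "x2")])
  expect_identical(attr(fit2, "rounds"), 1L)
  expect_length(attr(fit2, "removed"), 0L)
})

test_that("cross-validation folds partition the data and chase the noiseless limit", {
  d <- synth_activity_dataset(300, seed = 612, noise_sd = 0)
  X <- feature_matrix(d$guide_seq)
  cols <- names(mirscan_model("table2")$terms)
  cv <- cross_validate(d, n = 5, seed = 613, columns = cols, X = X)
  tab <- table(cv$fold)
  expect_length(tab, 5L)
  expect_lte(max(tab) - min(tab), 1L)
  expect_gt(cv$R2, 0.999)  # noiseless linear data
  # every record predicted exactly once, folds change with seed
  cv2 <- cross_validate(d, n = 5, seed = 614, columns = cols, X = X)
  expect_false(identical(cv$fold, cv2$fold))
  expect_length(cv$predictions, nrow(d))
  expect_error(cross_validate(d, n = 1), ">= 2")
  expect_error(cross_validate(d[1:3, ], n = 5, X = X[1:3, ]), "more folds")
})

test_that("ROC AUC equals the pair-counting oracle and hits the poles", {
  act <- c(rep(90, 5), rep(10, 5))
  expect_equal(roc_auc(c(6:10, 1:5), act)$auc, 1)
  expect_equal(roc_auc(c(1:5, 6:10), act)$auc, 0)
  set.seed(615)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    act <- runif(n, 0, 100)
    pred <- rnorm(n)
    if (sample(2, 1) == 1) pred <- round(pred)  # force ties sometimes
    r <- roc_auc(pred, act, efficiency_threshold = 50)
    expect_equal(r$auc, auc_oracle(pred, act >= 50), tolerance = 1e-12)
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  }
  expect_error(roc_auc(1:5, rep(90, 5)), "both classes")
})

test_that("binning is right-closed with empty bins reported", {
  v <- c(1, 2, 2, 3, 5)
  a <- c(10, 20, 30, 40, 50)
  b <- bin_by_feature(v, a, edges = c(0, 2, 4, 6))
  # value exactly on edge 2 falls in the (0, 2] bin
  expect_equal(b$n, c(3L, 1L, 1L))
  expect_equal(b$mean_activity, c(20, 40, 50))
  # single bin spanning everything
  b1 <- bin_by_feature(v, a, edges = c(0, 10))
  expect_equal(b1$n, 5L)
  expect_equal(b1$mean_activity, mean(a))
  # empty bin kept with count 0; out-of-range values excluded
  b2 <- bin_by_feature(v, a, edges = c(10, 20, 30))
  expect_equal(b2$n, c(0L, 0L))
  expect_identical(attr(b2, "n_excluded"), 5L)
  expect_error(bin_by_feature(v, a, edges = c(3, 3)), "strictly increasing")
  # planted bell-shaped activity vs dG reappears in the per-bin means
  set.seed(617)
  dg <- runif(2000, -55, -20)
  act <- 100 * exp(-(dg + 33)^2 / 50)
  edges <- seq(-55, -20, by = 5)
  bb <- bin_by_feature(dg, act, edges)
  planted <- vapply(seq_len(length(edges) - 1L), function(k) {
    sel <- dg > edges[k] & dg <= edges[k + 1L]
    mean(act[sel])
  }, numeric(1))
  expect_equal(bb$mean_activity, planted)
  expect_identical(which.max(bb$mean_activity),
                   which(edges == -35))  # peak bin covers (-35, -30]
})

test_that("activity tables round-trip through TSV with latent response", {
  d <- synth_activity_dataset(25, seed = 616)
  path <- tempfile(fileext = ".tsv")
  write_activity_table(d, path)
  d2 <- read_activity_table(path)
  expect_equal(d2$guide_seq, d$guide_seq)
  expect_equal(d2$silencing_percent, d$silencing_percent)
  expect_equal(activity_response(d2), d$ln_activity)
  # without the latent column the floored ln of percent is used
  d3 <- d2[, c("guide_seq", "silencing_percent")]
  expect_equal(activity_response(d3),
               log(pmax(d3$silencing_percent, 0.5)))
  bad <- tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(read_activity_table(bad), "needs columns")
})
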