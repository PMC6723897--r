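# NIPALS PLS1/PLS2, contiguous-block cross-validation, calibration metrics
# and PCA, checked against independent least-squares / SVD oracles on small
# full-rank instances.

test_that("PLS1 at full rank reproduces the OLS solution", {
  set.seed(10)
  X <- matrix(rnorm(30 * 5), 30)
  beta <- c(2, -1, 0.5, 3, -2)
  y <- as.numeric(X %*% beta) + 0.3 * rnorm(30)
  fit <- pls_fit(X, y, n_lv = 5)
  # oracle: ordinary least squares with intercept via the normal equations
  Xi <- cbind(1, X)
  coef_ols <- solve(crossprod(Xi), crossprod(Xi, y))
  pred_ols <- as.numeric(Xi %*% coef_ols)
  expect_equal(predict(fit, X), pred_ols, tolerance = 1e-6)
  # exact-linear response is recovered to numerical precision
  y_exact <- as.numeric(X %*% beta)
  fit2 <- pls_fit(X, y_exact, n_lv = 5)
  expect_lt(sqrt(mean((predict(fit2, X) - y_exact)^2)), 1e-8)
})

test_that("PLS1 is invariant to sample order and rejects degenerate input", {
  set.seed(11)
  X <- matrix(rnorm(25 * 8), 25)
  y <- rnorm(25)
  fit <- pls_fit(X, y, 3)
  perm <- sample(25)
  fit_p <- pls_fit(X[perm, ], y[perm], 3)
  expect_equal(fit_p$coef, fit$coef, tolerance = 1e-10)
  expect_error(pls_fit(X, rep(1, 25), 3), "zero-variance")
  expect_error(pls_fit(X, y, 30), "n_lv")
  expect_error(predict(fit, X[, 1:4]), "mismatch")
})

test_that("contiguous blocks split in order with sizes differing by at most one", {
  set.seed(12)
  X <- matrix(rnorm(120 * 6), 120)
  y <- rnorm(120)
  cv <- contiguous_block_cv(X, y, 2, n_splits = 30)
  expect_true(all(table(cv$block) == 4))
  expect_true(all(diff(cv$block) >= 0))   # contiguous in given order
  X31 <- matrix(rnorm(31 * 4), 31)
  cv31 <- contiguous_block_cv(X31, rnorm(31), 2, n_splits = 30)
  expect_equal(as.integer(sort(table(cv31$block), decreasing = TRUE)),
               c(2L, rep(1L, 29)))
  expect_error(contiguous_block_cv(X, y, 2, n_splits = 1), ">= 2")
  # noise-free linear data cross-validates to numerical zero
  y_lin <- as.numeric(X %*% c(1, -2, 0.5, 3, 1, -1))
  cv_lin <- contiguous_block_cv(X, y_lin, 6, n_splits = 30)
  expect_lt(cv_lin$rmsecv[6], 1e-6)
  expect_true(all(cv_lin$rmsecv >= 0))
})

test_that("calibration metrics match hand-computed residuals", {
  X <- cbind(c(1, 2, 3, 4), c(0, 1, 0, 1))
  y <- c(1.1, 2.0, 3.2, 3.9)
  fit <- pls_fit(X, y, 2)
  m <- pls_metrics(fit, X, y)
  res <- predict(fit, X) - y
  expect_equal(m$rmsec, sqrt(mean(res^2)), tolerance = 1e-12)
  expect_equal(m$r2c, 1 - sum(res^2) / sum((y - mean(y))^2), tolerance = 1e-12)
  # perfect predictions: RMSE 0, R2 1 (predicting a noiseless linear target)
  y_perfect <- as.numeric(X %*% c(1, 2)) + 3
  fitp <- pls_fit(X, y_perfect, 2)
  mp <- pls_metrics(fitp, X, y_perfect, X_test = X, y_test = y_perfect)
  expect_equal(mp$rmsec, 0, tolerance = 1e-8)
  expect_equal(mp$r2c, 1, tolerance = 1e-8)
  expect_equal(mp$rmsep, 0, tolerance = 1e-8)
  # a constant prediction scores R2 = 0 by definition
  expect_equal(1 - sum((y - mean(y))^2) / sum((y - mean(y))^2), 0)
})

test_that("PCA matches the SVD oracle and orders explained variance", {
  set.seed(13)
  X <- scale(matrix(rnorm(10 * 20), 10), center = TRUE, scale = FALSE)
  out <- pca(X, 3)
  sv <- svd(X)
  for (k in 1:3) {
    # loadings agree up to sign
    expect_equal(abs(sum(out$loadings[, k] * sv$v[, k])), 1, tolerance = 1e-8)
    expect_equal(abs(out$scores[, k]), abs(sv$u[, k] * sv$d[k]), tolerance = 1e-8)
  }
  expect_true(all(diff(out$explained) <= 1e-12))
  expect_lt(max(abs(crossprod(out$scores)[upper.tri(diag(3))])), 1e-8)
  # exact rank-1 data: first component carries all the variance
  r1 <- tcrossprod(rnorm(8), rnorm(15))
  r1 <- scale(r1, center = TRUE, scale = FALSE)
  expect_equal(pca(r1, 1)$explained[1], 1, tolerance = 1e-10)
  expect_error(pca(r1, 5), "rank")
})

test_that("direct PLS2 with all components equals multi-response OLS", {
  set.seed(14)
  X <- matrix(rnorm(40 * 3), 40)
  B <- matrix(rnorm(3 * 6), 3)
  Y <- X %*% B + matrix(rnorm(40 * 6, sd = 0.1), 40)
  fit <- pls_direct_fit(X, Y, n_lv = 3)
  Xi <- cbind(1, X)
  B_ols <- solve(crossprod(Xi), crossprod(Xi, Y))
  expect_equal(predict(fit, X), Xi %*% B_ols, tolerance = 1e-6,
               ignore_attr = TRUE)
  # at the input means the centred model predicts the mean profile
  expect_equal(as.numeric(predict(fit, matrix(colMeans(X), 1))),
               colMeans(predict(fit, X)), tolerance = 1e-6)
  expect_error(pls_direct_fit(X, Y, n_lv = 4), "input dimension")
})

test_that("linear profile maps are easy for direct PLS; threshold maps are not", {
  set.seed(15)
  n <- 60
  inputs <- cbind(runif(n, 6, 10), runif(n, 10, 30), runif(n, 60, 130))
  t_grid <- dissolution_time_grid()[seq(1, 53, by = 4)]
  lin_profiles <- outer(inputs[, 1], t_grid / 1440 * 10) +
    outer(inputs[, 2], rep(1, length(t_grid)))
  fit_lin <- pls_direct_fit(inputs, lin_profiles, 3)
  expect_lt(sqrt(mean((predict(fit_lin, inputs) - lin_profiles)^2)), 0.2)
  # strongly nonlinear polymer effect leaves large residuals at the extremes
  nl_profiles <- t(vapply(seq_len(n), function(i)
    simulate_profile(inputs[i, 1], inputs[i, 2], inputs[i, 3], t_grid),
    numeric(length(t_grid))))
  fit_nl <- pls_direct_fit(inputs, nl_profiles, 3)
  res <- predict(fit_nl, inputs) - nl_profiles
  lo <- inputs[, 2] < 12
  expect_gt(sqrt(mean(res[lo, ]^2)), 5)
})
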