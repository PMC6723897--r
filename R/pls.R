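# NIPALS partial least squares: single-response PLS1 for composition
# calibration, multi-response PLS2 for the direct profile baseline,
# contiguous-block cross-validation and the RMSE/R^2 calibration metrics.

#' Fit a PLS1 model (NIPALS)
#'
#' Single-response NIPALS partial least squares on column-centred `X` and
#' centred `y`, with deflation after each latent variable. Coefficient
#' vectors are stored for every component count 1..`n_lv`, so predictions
#' at any smaller complexity come from the same fit.
#'
#' @param X Numeric predictor matrix (samples x channels).
#' @param y Numeric response vector.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @return An object of class `pls_model`: centres, weight/loading/score
#'   matrices `W`, `P`, `Q`, `T`, and `coef` (channels x `n_lv`, cumulative
#'   regression vectors).
#' @export
pls_fit <- function(X, y, n_lv) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y), n >= n_lv + 1)
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stop("n_lv must be in 1..min(samples - 1, channels)")
  if (stats::sd(y) == 0) stop("zero-variance response")
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xd <- sweep(X, 2, x_mean); yd <- y - y_mean
  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { n_lv <- a - 1L; break }
    w <- w / nw
    t <- as.numeric(Xd %*% w)
    tt <- sum(t^2)
    pl <- as.numeric(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
  }
  if (n_lv < 1) stop("response is orthogonal to predictors")
  W <- W[, seq_len(n_lv), drop = FALSE]; P <- P[, seq_len(n_lv), drop = FALSE]
  Tm <- Tm[, seq_len(n_lv), drop = FALSE]; q <- q[seq_len(n_lv)]
  coef <- matrix(0, p, n_lv)
  for (a in seq_len(n_lv)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    coef[, a] <- Wa %*% solve(crossprod(P[, seq_len(a), drop = FALSE], Wa),
                              q[seq_len(a)])
  }
  structure(list(n_lv = n_lv, x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, Q = q, T = Tm, coef = coef),
            class = "pls_model")
}

#' Predict from a PLS1 model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the same channels as the training data.
#' @param n_lv Component count to predict with (default: the fitted count).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("channel-grid mismatch: model has ", length(object$x_mean),
         " channels, data has ", ncol(newdata))
  stopifnot(n_lv >= 1, n_lv <= object$n_lv)
  object$y_mean + as.numeric(sweep(newdata, 2, object$x_mean) %*%
                               object$coef[, n_lv])
}

#' Contiguous-block cross-validation of a PLS1 model
#'
#' Partitions the samples, in their given (acquisition) order, into
#' `n_splits` contiguous blocks whose sizes differ by at most one; each
#' block is predicted by a model fitted on the remainder. Out-of-block
#' residuals are pooled into RMSECV and R^2cv per component count.
#'
#' @param X,y Training data.
#' @param n_lv_max Largest component count to evaluate.
#' @param n_splits Number of blocks (the study uses 30).
#' @return List with `rmsecv` and `r2cv` (length `n_lv_max`), and `pred`
#'   (samples x `n_lv_max` out-of-block predictions).
#' @export
contiguous_block_cv <- function(X, y, n_lv_max, n_splits = 30) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n_splits < 2) stop("n_splits must be >= 2")
  if (n_splits > n) stop("n_splits exceeds sample count")
  sizes <- rep(n %/% n_splits, n_splits)
  extra <- n %% n_splits
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block <- rep(seq_len(n_splits), sizes)
  pred <- matrix(NA_real_, n, n_lv_max)
  for (b in seq_len(n_splits)) {
    test <- block == b
    a_max <- min(n_lv_max, sum(!test) - 1L, ncol(X))
    fit <- pls_fit(X[!test, , drop = FALSE], y[!test], a_max)
    a_max <- fit$n_lv
    for (a in seq_len(a_max))
      pred[test, a] <- predict(fit, X[test, , drop = FALSE], n_lv = a)
    if (a_max < n_lv_max)
      pred[test, (a_max + 1L):n_lv_max] <- pred[test, a_max]
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  sstot <- sum((y - mean(y))^2)
  r2cv <- 1 - colSums((pred - y)^2) / sstot
  list(rmsecv = rmsecv, r2cv = r2cv, pred = pred, block = block)
}

#' Pick the latent-variable count from a cross-validation curve
#'
#' Smallest component count whose RMSECV is within `tol` (relative) of the
#' minimum — a parsimony tie-break toward fewer latent variables.
#'
#' @param rmsecv RMSECV per component count.
#' @param tol Relative tolerance (default 2 %).
#' @return Integer component count.
#' @export
choose_n_lv <- function(rmsecv, tol = 0.02) {
  which(rmsecv <= (1 + tol) * min(rmsecv))[1]
}

#' Calibration / cross-validation / prediction metrics
#'
#' RMSE is the root mean squared residual on the respective set; R^2 is
#' `1 - SSres/SStot` with `SStot` about that set's own mean.
#'
#' @param model A fitted `pls_model`.
#' @param X_cal,y_cal Calibration set.
#' @param X_test,y_test Optional external test set.
#' @param cv Optional result of [contiguous_block_cv()]; its values at the
#'   model's component count are reported.
#' @return A one-row data frame: `n_lv`, `rmsec`, `r2c`, and (when
#'   available) `rmsecv`, `r2cv`, `rmsep`, `r2p`.
#' @export
pls_metrics <- function(model, X_cal, y_cal, X_test = NULL, y_test = NULL,
                        cv = NULL) {
  if (!length(y_cal)) stop("empty calibration set")
  rmse <- function(res) sqrt(mean(res^2))
  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  pc <- predict(model, X_cal)
  out <- data.frame(n_lv = model$n_lv, rmsec = rmse(pc - y_cal),
                    r2c = r2(y_cal, pc))
  if (!is.null(cv)) {
    out$rmsecv <- cv$rmsecv[model$n_lv]
    out$r2cv <- cv$r2cv[model$n_lv]
  }
  if (!is.null(X_test)) {
    if (!length(y_test)) stop("empty test set")
    pt <- predict(model, X_test)
    out$rmsep <- rmse(pt - y_test)
    out$r2p <- r2(y_test, pt)
  }
  out
}

#' Principal component analysis of a centred spectral matrix
#'
#' Thin wrapper around [stats::prcomp()] returning scores, orthonormal
#' loadings and explained-variance fractions for the leading components.
#'
#' @param x Centred numeric matrix (or a [spectrum_set()], whose intensity
#'   matrix is used).
#' @param n_pc Number of components (must not exceed the matrix rank).
#' @return List with `scores`, `loadings`, `explained` (fractions of total
#'   variance, nonincreasing).
#' @export
pca <- function(x, n_pc) {
  if (inherits(x, "spectrum_set")) x <- x$intensities
  x <- as.matrix(x)
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_pc > rank) stop("n_pc (", n_pc, ") exceeds matrix rank (", rank, ")")
  idx <- seq_len(n_pc)
  list(scores = pr$x[, idx, drop = FALSE],
       loadings = pr$rotation[, idx, drop = FALSE],
       explained = ev[idx] / sum(ev))
}

#' Direct PLS2 profile baseline
#'
#' Multi-response NIPALS PLS from the three tablet descriptors (drug %,
#' polymer %, compression force) to the 53-point dissolution profile — the
#' linear baseline the network is benchmarked against. Inputs are
#' autoscaled (centred, divided by their standard deviation) and targets
#' mean centred, both on the training data.
#'
#' @param inputs Samples x 3 matrix.
#' @param profiles Samples x 53 target matrix.
#' @param n_lv Latent variables, at most `ncol(inputs)`.
#' @return An object of class `pls_direct`.
#' @export
pls_direct_fit <- function(inputs, profiles, n_lv = 3) {
  X <- as.matrix(inputs); Y <- as.matrix(profiles)
  stopifnot(nrow(X) == nrow(Y))
  if (n_lv > ncol(X)) stop("n_lv must not exceed the input dimension (",
                           ncol(X), ")")
  x_mean <- colMeans(X); x_sd <- apply(X, 2, stats::sd)
  if (any(x_sd == 0)) stop("zero-variance input column")
  y_mean <- colMeans(Y)
  Xd <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  Yd <- sweep(Y, 2, y_mean)
  p <- ncol(Xd); m <- ncol(Yd)
  W <- P <- matrix(0, p, n_lv); Q <- matrix(0, m, n_lv)
  for (a in seq_len(n_lv)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    for (it in seq_len(500)) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      t <- as.numeric(Xd %*% w)
      q <- as.numeric(crossprod(Yd, t)) / sum(t^2)
      u_new <- as.numeric(Yd %*% q) / sum(q^2)
      if (sum((u_new - u)^2) < 1e-24 * sum(u^2)) { u <- u_new; break }
      u <- u_new
    }
    tt <- sum(t^2)
    pl <- as.numeric(crossprod(Xd, t)) / tt
    Xd <- Xd - tcrossprod(t, pl)
    Yd <- Yd - tcrossprod(t, q)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(n_lv = n_lv, x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
                 B = B), class = "pls_direct")
}

#' @export
predict.pls_direct <- function(object, newdata, ...) {
  Xd <- sweep(sweep(as.matrix(newdata), 2, object$x_mean), 2, object$x_sd, "/")
  sweep(Xd %*% object$B, 2, object$y_mean, "+")
}
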