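# Feed-forward 3 -> H -> 53 profile network: tanh hidden layer, linear
# output, min-max [-1, 1] input/target scaling, analytic Jacobian, and two
# trainers — Levenberg-Marquardt with validation early stopping, and
# Bayesian regularization (evidence approximation, effective parameter
# count gamma) — plus the hidden-neuron sweep / replicate protocol.

#' Create an untrained profile network
#'
#' Weights and biases are initialised to small uniform values scaled by the
#' layer fan-in, from `seed`. Scaling maps are unfitted until training.
#'
#' @param hidden Hidden-neuron count H (the study sweeps 1..10).
#' @param n_in Input dimension (drug %, polymer %, force MPa).
#' @param n_out Output dimension (53 dissolution points).
#' @param seed Integer seed for the initial weights.
#' @return An object of class `profile_ann`.
#' @export
ann_new <- function(hidden, n_in = 3, n_out = 53, seed = 1L) {
  stopifnot(hidden >= 1, n_in >= 1, n_out >= 1)
  set.seed(seed)
  W1 <- matrix(stats::runif(hidden * n_in, -1, 1) / sqrt(n_in), hidden, n_in)
  b1 <- stats::runif(hidden, -1, 1) / sqrt(n_in)
  W2 <- matrix(stats::runif(n_out * hidden, -1, 1) / sqrt(hidden), n_out, hidden)
  b2 <- stats::runif(n_out, -1, 1) / sqrt(hidden)
  structure(list(hidden = as.integer(hidden), n_in = n_in, n_out = n_out,
                 W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 x_scale = NULL, y_scale = NULL, seed = seed,
                 trainer = NULL, diagnostics = NULL),
            class = "profile_ann")
}

# --- min-max [-1, 1] feature scaling (fitted on training data only) -------
minmax_fit <- function(M) {
  lo <- apply(M, 2, min); hi <- apply(M, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1   # constant feature maps to -1
  list(lo = lo, rng = rng)
}
minmax_apply <- function(M, s) sweep(sweep(M, 2, s$lo), 2, s$rng / 2, "/") - 1
minmax_invert <- function(M, s) sweep(sweep(M + 1, 2, s$rng / 2, "*"), 2, s$lo, "+")

# --- parameter vector packing ---------------------------------------------
ann_pack <- function(net) c(net$W1, net$b1, net$W2, net$b2)
ann_unpack <- function(net, theta) {
  H <- net$hidden; I <- net$n_in; K <- net$n_out
  i <- 0L
  net$W1 <- matrix(theta[i + seq_len(H * I)], H, I); i <- i + H * I
  net$b1 <- theta[i + seq_len(H)];                  i <- i + H
  net$W2 <- matrix(theta[i + seq_len(K * H)], K, H); i <- i + K * H
  net$b2 <- theta[i + seq_len(K)]
  net
}

# forward pass in scaled space; returns hidden activations too
ann_forward_scaled <- function(net, Xs) {
  A1 <- tcrossprod(Xs, net$W1)
  A1 <- sweep(A1, 2, net$b1, "+")
  Hm <- tanh(A1)
  Ys <- sweep(tcrossprod(Hm, net$W2), 2, net$b2, "+")
  list(H = Hm, Y = Ys)
}

#' Network forward pass on raw inputs
#'
#' Scales the inputs with the fitted map, runs the tanh-hidden /
#' linear-output network, and inverse-scales the outputs back to % released.
#'
#' @param net A trained (or at least scale-fitted) `profile_ann`.
#' @param inputs Matrix (or single vector) of raw inputs, `n_in` columns.
#' @return Matrix of predicted profiles (rows = tablets, `n_out` columns).
#' @export
ann_forward <- function(net, inputs) {
  if (is.null(net$x_scale) || is.null(net$y_scale))
    stop("scaling maps are unfitted; train the network first")
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1)
  Xs <- minmax_apply(as.matrix(inputs), net$x_scale)
  minmax_invert(ann_forward_scaled(net, Xs)$Y, net$y_scale)
}

# residual vector (k fastest within sample) and Jacobian of predictions
# w.r.t. the packed parameters, in scaled space
ann_jacobian <- function(net, Xs, fwd = NULL) {
  if (is.null(fwd)) fwd <- ann_forward_scaled(net, Xs)
  Hm <- fwd$H
  n <- nrow(Xs); I <- ncol(Xs); H <- net$hidden; K <- net$n_out
  D <- 1 - Hm^2
  Np <- H * I + H + K * H + K
  J <- matrix(0, n * K, Np)
  rows <- seq_len(n * K)
  for (i in seq_len(I)) for (j in seq_len(H))
    J[, (i - 1L) * H + j] <- rep(D[, j] * Xs[, i], each = K) * net$W2[, j]
  off <- H * I
  for (j in seq_len(H))
    J[, off + j] <- rep(D[, j], each = K) * net$W2[, j]
  off <- off + H
  kk <- rep(seq_len(K), n)
  for (j in seq_len(H))
    J[cbind(rows, off + (j - 1L) * K + kk)] <- rep(Hm[, j], each = K)
  off <- off + K * H
  J[cbind(rows, off + kk)] <- 1
  J
}

ann_residuals <- function(net, Xs, Ts, fwd = NULL) {
  if (is.null(fwd)) fwd <- ann_forward_scaled(net, Xs)
  as.vector(t(fwd$Y - Ts))
}

#' Train with Levenberg-Marquardt and validation early stopping
#'
#' Minimises the sum of squared residuals in scaled space. Each epoch
#' computes the analytic Jacobian and solves
#' `(J'J + mu I) delta = J'r`; `mu` is divided by 10 on an accepted step
#' and multiplied by 10 on a rejected one (trained mean squared error is
#' therefore nonincreasing over accepted epochs). Training stops when the
#' validation MSE has risen for `patience` consecutive epochs (the weights
#' with the best validation MSE are returned), when `mu` exceeds `mu_max`,
#' or at `max_epochs`.
#'
#' @param net A `profile_ann` from [ann_new()].
#' @param X_train,Y_train Raw training inputs/targets (scalers are fitted
#'   here).
#' @param X_val,Y_val Validation set for early stopping (optional: `NULL`
#'   disables early stopping).
#' @param max_epochs,patience,mu0,mu_max Optimiser controls.
#' @return The trained `profile_ann`; `$diagnostics` holds the MSE traces.
#' @export
train_lm <- function(net, X_train, Y_train, X_val = NULL, Y_val = NULL,
                     max_epochs = 300, patience = 6, mu0 = 1e-3,
                     mu_max = 1e10) {
  X_train <- as.matrix(X_train); Y_train <- as.matrix(Y_train)
  if (nrow(X_train) < net$hidden + 1)
    stop("need at least hidden + 1 training samples")
  net$x_scale <- minmax_fit(X_train)
  net$y_scale <- minmax_fit(Y_train)
  Xs <- minmax_apply(X_train, net$x_scale)
  Ts <- minmax_apply(Y_train, net$y_scale)
  has_val <- !is.null(X_val) && nrow(as.matrix(X_val)) > 0
  if (has_val) {
    Xvs <- minmax_apply(as.matrix(X_val), net$x_scale)
    Tvs <- minmax_apply(as.matrix(Y_val), net$y_scale)
  }
  theta <- ann_pack(net)
  Np <- length(theta)
  r <- ann_residuals(net, Xs, Ts)
  E <- sum(r^2)
  mu <- mu0
  best_val <- Inf; best_theta <- theta; rises <- 0L
  mse_trace <- val_trace <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    J <- ann_jacobian(net, Xs)
    g <- crossprod(J, r)
    A <- crossprod(J)
    improved <- FALSE
    while (mu <= mu_max) {
      step <- tryCatch(solve(A + diag(mu, Np), g), error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta - as.numeric(step)
        net_new <- ann_unpack(net, theta_new)
        r_new <- ann_residuals(net_new, Xs, Ts)
        E_new <- sum(r_new^2)
        if (E_new < E) {
          theta <- theta_new; net <- net_new; r <- r_new; E <- E_new
          mu <- max(mu / 10, 1e-20)
          improved <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!improved) break
    mse_trace <- c(mse_trace, E / length(r))
    if (has_val) {
      vr <- ann_residuals(net, Xvs, Tvs)
      vmse <- mean(vr^2)
      val_trace <- c(val_trace, vmse)
      if (vmse < best_val) {
        best_val <- vmse; best_theta <- theta; rises <- 0L
      } else {
        rises <- rises + 1L
        if (rises >= max(patience, 1L)) break
      }
      if (patience == 0 && vmse >= best_val) break
    }
    if (E / length(r) < 1e-12) break
  }
  if (has_val) net <- ann_unpack(net, best_theta)
  net$trainer <- "LM"
  net$diagnostics <- list(mse = mse_trace, val_mse = val_trace,
                          final_mse = if (has_val && length(val_trace))
                            min(val_trace) else E / length(r),
                          epochs = length(mse_trace))
  net
}

#' Train with Bayesian regularization
#'
#' Minimises `F = beta * E_D + alpha * E_W` (`E_D` the sum of squared
#' residuals in scaled space, `E_W` the sum of squared weights) by
#' Levenberg-Marquardt steps. After each accepted step the evidence
#' approximation updates the effective parameter count
#' `gamma = N_w - alpha * trace(H^-1)` with `H = beta J'J + alpha I`, then
#' `alpha = gamma / (2 E_W)` and `beta = (n_obs - gamma) / (2 E_D)`.
#' There is no validation early stopping.
#'
#' @param net A `profile_ann`.
#' @param X_train,Y_train Raw training data.
#' @param max_epochs,mu0,mu_max Optimiser controls.
#' @return Trained `profile_ann`; `$diagnostics` records the `gamma`,
#'   `alpha`, `beta` and objective traces.
#' @export
train_br <- function(net, X_train, Y_train, max_epochs = 150, mu0 = 1e-3,
                     mu_max = 1e10) {
  X_train <- as.matrix(X_train); Y_train <- as.matrix(Y_train)
  if (nrow(X_train) < net$hidden + 1)
    stop("need at least hidden + 1 training samples")
  net$x_scale <- minmax_fit(X_train)
  net$y_scale <- minmax_fit(Y_train)
  Xs <- minmax_apply(X_train, net$x_scale)
  Ts <- minmax_apply(Y_train, net$y_scale)
  theta <- ann_pack(net)
  Np <- length(theta)
  n_obs <- nrow(Xs) * net$n_out
  r <- ann_residuals(net, Xs, Ts)
  ED <- sum(r^2); EW <- sum(theta^2)
  alpha <- 0; beta <- 1
  Fobj <- beta * ED + alpha * EW
  mu <- mu0
  gamma_trace <- mse_trace <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    J <- ann_jacobian(net, Xs)
    g <- beta * crossprod(J, r) + alpha * theta
    A <- beta * crossprod(J)
    improved <- FALSE
    while (mu <= mu_max) {
      step <- tryCatch(solve(A + diag(alpha + mu, Np), g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta - as.numeric(step)
        net_new <- ann_unpack(net, theta_new)
        r_new <- ann_residuals(net_new, Xs, Ts)
        ED_new <- sum(r_new^2); EW_new <- sum(theta_new^2)
        F_new <- beta * ED_new + alpha * EW_new
        if (F_new < Fobj) {
          theta <- theta_new; net <- net_new; r <- r_new
          ED <- ED_new; EW <- EW_new; Fobj <- F_new
          mu <- max(mu / 10, 1e-20)
          improved <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!improved) break
    # evidence approximation hyperparameter update
    Hreg <- A + diag(alpha, Np)
    tr_inv <- tryCatch(sum(diag(chol2inv(chol(Hreg)))),
                       error = function(e) {
                         warning("Hessian inversion failed; ridge-stabilised")
                         sum(diag(solve(Hreg + diag(1e-8 * mean(diag(Hreg)), Np))))
                       })
    gamma <- Np - alpha * tr_inv
    gamma <- min(max(gamma, 0), Np)
    alpha <- gamma / (2 * max(EW, 1e-300))
    beta <- max(n_obs - gamma, 1e-3) / (2 * max(ED, 1e-300))
    Fobj <- beta * ED + alpha * EW
    gamma_trace <- c(gamma_trace, gamma)
    mse_trace <- c(mse_trace, ED / n_obs)
    if (ED / n_obs < 1e-12) break
  }
  net$trainer <- "BR"
  net$diagnostics <- list(mse = mse_trace, gamma = gamma_trace,
                          alpha = alpha, beta = beta,
                          final_mse = ED / n_obs,
                          gamma_final = if (length(gamma_trace))
                            gamma_trace[length(gamma_trace)] else Np,
                          epochs = length(mse_trace))
  net
}

#' Hidden-neuron sweep with replicate training runs
#'
#' For every hidden-neuron count in `hidden_values`, trains `runs`
#' replicate networks, each with a fresh seeded 70/15/15
#' train/validation/internal-test split of the training tablets (the
#' validation part drives LM early stopping; BR uses only the 70 %), then
#' predicts the external test tablets from their inputs. Each run is scored
#' by its summed external RMSEP (per-tablet profile RMSEP summed over test
#' tablets). The sweep records the mean summed RMSEP per H and keeps the
#' single best run overall as the selected model. All randomness derives
#' from `seed`.
#'
#' @param X_train,Y_train Training tablets' inputs (nominal composition +
#'   measured force) and measured 53-point profiles.
#' @param X_test,Y_test External test tablets' inputs (PLS-predicted
#'   composition + measured force) and their profiles.
#' @param trainer `"LM"` or `"BR"`.
#' @param runs Replicate runs per H (the study uses 100).
#' @param hidden_values Hidden-neuron counts to sweep (the study uses 1:10).
#' @param seed Master seed.
#' @param max_epochs Epoch cap passed to the trainer.
#' @return An object of class `ann_sweep`: `summary` (data frame: hidden,
#'   mean/min summed RMSEP), `best` (net, hidden, run, summed RMSEP),
#'   `runs` (per-run bookkeeping).
#' @export
neuron_sweep <- function(X_train, Y_train, X_test, Y_test, trainer = c("BR", "LM"),
                         runs = 100, hidden_values = 1:10, seed = 1L,
                         max_epochs = if (trainer == "BR") 150 else 300) {
  trainer <- match.arg(trainer)
  X_train <- as.matrix(X_train); Y_train <- as.matrix(Y_train)
  X_test <- as.matrix(X_test); Y_test <- as.matrix(Y_test)
  if (!nrow(X_test)) stop("empty external test set")
  n <- nrow(X_train)
  total <- runs * length(hidden_values)
  seeds <- matrix(derive_seeds(seed, 2L * total), ncol = 2)
  all_runs <- vector("list", total)
  idx <- 0L
  for (h in hidden_values) {
    for (rrun in seq_len(runs)) {
      idx <- idx + 1L
      split_seed <- seeds[idx, 1]; init_seed <- seeds[idx, 2]
      set.seed(split_seed)
      perm <- sample.int(n)
      n_tr <- round(0.70 * n); n_va <- round(0.15 * n)
      i_tr <- perm[seq_len(n_tr)]
      i_va <- perm[n_tr + seq_len(n_va)]
      net <- ann_new(h, ncol(X_train), ncol(Y_train), seed = init_seed)
      net <- if (trainer == "LM")
        train_lm(net, X_train[i_tr, , drop = FALSE], Y_train[i_tr, , drop = FALSE],
                 X_train[i_va, , drop = FALSE], Y_train[i_va, , drop = FALSE],
                 max_epochs = max_epochs)
      else
        train_br(net, X_train[i_tr, , drop = FALSE], Y_train[i_tr, , drop = FALSE],
                 max_epochs = max_epochs)
      pred <- ann_forward(net, X_test)
      per_tablet <- sqrt(rowMeans((pred - Y_test)^2))
      all_runs[[idx]] <- list(hidden = h, run = rrun, net = net,
                              split_seed = split_seed, init_seed = init_seed,
                              summed_rmsep = sum(per_tablet))
    }
  }
  sums <- vapply(all_runs, `[[`, numeric(1), "summed_rmsep")
  hs <- vapply(all_runs, `[[`, numeric(1), "hidden")
  summary <- data.frame(
    hidden = hidden_values,
    mean_summed_rmsep = vapply(hidden_values, function(h) mean(sums[hs == h]),
                               numeric(1)),
    min_summed_rmsep = vapply(hidden_values, function(h) min(sums[hs == h]),
                              numeric(1))
  )
  best_idx <- which.min(sums)
  structure(list(summary = summary,
                 best = all_runs[[best_idx]],
                 runs = lapply(all_runs, function(r) r[c("hidden", "run",
                                                         "split_seed", "init_seed",
                                                         "summed_rmsep")]),
                 trainer = trainer, seed = seed),
            class = "ann_sweep")
}
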