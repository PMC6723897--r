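# Genetic-algorithm wavelength-window selection for PLS calibration:
# chromosomes are bit vectors over contiguous channel windows, fitness is
# the contiguous-block cross-validated RMSECV of a PLS model (best
# component count up to the configured maximum) on the selected channels.

#' Genetic-algorithm configuration
#'
#' Defaults follow the study's stated settings (population 64, window width
#' 10 channels, at most 6 latent variables, best of 3 replicate runs); the
#' remaining internals are conventional GA-PLS choices and fully
#' configurable.
#'
#' @param population Even population size.
#' @param window_width Channels per selectable window (>= 1).
#' @param max_lv Largest PLS component count tried on a selection.
#' @param replicate_runs Independent GA restarts; the best is returned.
#' @param generations Generations per run.
#' @param crossover_rate Probability of single-point crossover (at window
#'   boundaries) per mating pair.
#' @param mutation_rate Per-window bit-flip probability.
#' @param tournament_size Selection tournament size.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param init_prob Probability a window starts selected.
#' @param n_splits Contiguous-block CV splits used in the fitness.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 64, window_width = 10, max_lv = 6,
                      replicate_runs = 3, generations = 100,
                      crossover_rate = 0.5, mutation_rate = 0.01,
                      tournament_size = 2, elitism = 1, init_prob = 0.3,
                      n_splits = 30) {
  stopifnot(population %% 2 == 0, window_width >= 1, max_lv >= 1,
            replicate_runs >= 1, generations >= 1)
  structure(as.list(environment()), class = "ga_config")
}

# internal: channel windows of fixed width; remainder joins the last window
ga_windows <- function(p, width) {
  n_win <- p %/% width
  if (n_win < 1) stop("fewer channels than one window")
  win <- split(seq_len(n_win * width), rep(seq_len(n_win), each = width))
  if (p > n_win * width)
    win[[n_win]] <- c(win[[n_win]], seq(n_win * width + 1L, p))
  win
}

# internal: CV fitness of a window-selection chromosome
ga_fitness <- function(bits, windows, X, y, config) {
  if (!any(bits)) return(Inf)
  cols <- unlist(windows[bits], use.names = FALSE)
  a_max <- min(config$max_lv, length(cols), nrow(X) - 1L)
  cv <- contiguous_block_cv(X[, cols, drop = FALSE], y, a_max,
                            n_splits = config$n_splits)
  min(cv$rmsecv)
}

#' GA wavelength-window selection
#'
#' Evolves bit-vector chromosomes over contiguous channel windows with
#' tournament selection, single-point crossover at window boundaries,
#' per-window mutation and elitism. Fitness is the minimum contiguous-block
#' RMSECV over component counts up to `max_lv` on the selected channels.
#' `replicate_runs` independent runs are performed and the best returned.
#' All randomness derives from `seed`.
#'
#' @param X,y Training data (channels >= `window_width`).
#' @param config A [ga_config()].
#' @param seed Integer seed.
#' @return List with `mask` (logical over channels), `window_bits`,
#'   `rmsecv` (best fitness), `model` (PLS refit on the selection at its
#'   CV-chosen component count), `n_lv` and `history` (best fitness per
#'   generation, per replicate).
#' @export
ga_select <- function(X, y, config = ga_config(), seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X)
  if (p < config$window_width) stop("channels < window_width")
  windows <- ga_windows(p, config$window_width)
  n_win <- length(windows)
  run_seeds <- derive_seeds(seed, config$replicate_runs)
  runs <- lapply(seq_len(config$replicate_runs), function(r) {
    set.seed(run_seeds[r])
    pop <- matrix(stats::runif(config$population * n_win) < config$init_prob,
                  config$population, n_win)
    pop[rowSums(pop) == 0, 1] <- TRUE
    fit <- apply(pop, 1, ga_fitness, windows, X, y, config)
    history <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      ord <- order(fit)
      new_pop <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
      while (nrow(new_pop) < config$population) {
        pick <- function() {
          cand <- sample.int(config$population, config$tournament_size)
          cand[which.min(fit[cand])]
        }
        a <- pop[pick(), ]; b <- pop[pick(), ]
        if (stats::runif(1) < config$crossover_rate && n_win > 1) {
          cut <- sample.int(n_win - 1L, 1)
          tmp <- a
          a <- c(a[seq_len(cut)], b[(cut + 1L):n_win])
          b <- c(b[seq_len(cut)], tmp[(cut + 1L):n_win])
        }
        flip_a <- stats::runif(n_win) < config$mutation_rate
        flip_b <- stats::runif(n_win) < config$mutation_rate
        new_pop <- rbind(new_pop, xor(a, flip_a), xor(b, flip_b))
      }
      pop <- new_pop[seq_len(config$population), , drop = FALSE]
      fit <- apply(pop, 1, ga_fitness, windows, X, y, config)
      # elitism guarantees the running best never worsens
      history[g] <- min(fit)
    }
    best <- which.min(fit)
    list(bits = pop[best, ], fitness = fit[best], history = history)
  })
  best_run <- runs[[which.min(vapply(runs, `[[`, numeric(1), "fitness"))]]
  cols <- unlist(windows[best_run$bits], use.names = FALSE)
  mask <- seq_len(p) %in% cols
  a_max <- min(config$max_lv, length(cols), nrow(X) - 1L)
  cv <- contiguous_block_cv(X[, cols, drop = FALSE], y, a_max,
                            n_splits = config$n_splits)
  n_lv <- choose_n_lv(cv$rmsecv)
  model <- pls_fit(X[, cols, drop = FALSE], y, n_lv)
  list(mask = mask, window_bits = best_run$bits, rmsecv = best_run$fitness,
       model = model, n_lv = n_lv,
       history = lapply(runs, `[[`, "history"))
}
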