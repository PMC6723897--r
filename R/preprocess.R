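# Spectral pretreatment operators: region exclusion, asymmetric least
# squares (Whittaker) baseline removal, SNV, MSC, Savitzky-Golay
# derivatives, mean centering, and recipe replay with fitted state so the
# identical transform is applied to held-out spectra.

#' Retain spectral regions
#'
#' Keeps only channels whose wavenumber lies inside the union of the closed
#' keep windows; channel order is preserved.
#'
#' @param s A [spectrum_set()].
#' @param keep_windows List of `c(lo, hi)` wavenumber intervals (cm^-1).
#' @return A reduced `spectrum_set`.
#' @export
exclude_regions <- function(s, keep_windows) {
  stopifnot(inherits(s, "spectrum_set"))
  if (is.numeric(keep_windows) && length(keep_windows) == 2)
    keep_windows <- list(keep_windows)
  mask <- Reduce(`|`, lapply(keep_windows, function(w) {
    stopifnot(length(w) == 2, w[1] <= w[2])
    s$wavenumbers >= w[1] & s$wavenumbers <= w[2]
  }))
  if (!any(mask)) stop("no channels retained")
  out <- spectrum_set(s$wavenumbers[mask],
                      s$intensities[, mask, drop = FALSE],
                      s$sample_ids, s$modality, s$provenance)
  append_provenance(out, "exclude_regions", list(keep = keep_windows))
}

# internal: AsLS baseline of one spectrum (sparse Whittaker solver)
asls_one <- function(y, p, lam, max_iter, tol) {
  n <- length(y)
  D <- Matrix::diff(Matrix::Diagonal(n), differences = 2)
  P <- lam * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(x = w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (mean(w_new != w) < tol) break
    w <- w_new
  }
  z
}

#' Asymmetric least squares (Whittaker) baseline correction
#'
#' Per spectrum, finds the smooth baseline `z` minimising
#' `sum(w_i (y_i - z_i)^2) + lam * sum((diff(z, differences = 2))^2)` with
#' asymmetric weights `w_i = p` where `y_i > z_i` and `1 - p` otherwise
#' (iterated from `w = 1`), and returns `y - z`. Iteration stops when fewer
#' than a `tol` fraction of weights change, or after `max_iter` rounds.
#'
#' @param s A [spectrum_set()] with at least 3 channels.
#' @param p Asymmetry in (0, 1); the study setting is 0.001.
#' @param lam Smoothness penalty > 0; the study setting is 1e4.
#' @param max_iter,tol Weight-update iteration controls.
#' @return Baseline-corrected `spectrum_set`.
#' @export
asls_baseline <- function(s, p = 0.001, lam = 1e4, max_iter = 50, tol = 1e-6) {
  stopifnot(inherits(s, "spectrum_set"), p > 0, p < 1, lam > 0)
  if (length(s$wavenumbers) < 3) stop("AsLS needs at least 3 channels")
  corrected <- t(apply(s$intensities, 1, function(y)
    y - asls_one(y, p, lam, max_iter, tol)))
  s$intensities <- corrected
  append_provenance(s, "asls_baseline", list(p = p, lam = lam))
}

#' Standard normal variate
#'
#' Per spectrum: subtract its mean, divide by its sample standard deviation
#' (n-1 denominator).
#'
#' @param s A [spectrum_set()].
#' @return SNV-normalised `spectrum_set`.
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  mu <- rowMeans(s$intensities)
  sd <- apply(s$intensities, 1, stats::sd)
  if (any(sd == 0))
    stop("zero-variance spectrum: ", paste(s$sample_ids[sd == 0], collapse = ", "))
  s$intensities <- (s$intensities - mu) / sd
  append_provenance(s, "snv", list())
}

#' Multiplicative signal correction
#'
#' Per spectrum `y`, fits `y = a + b * ref` by ordinary least squares over
#' the retained channels and returns `(y - a) / b`. The reference defaults
#' to the mean spectrum of the given (training) set; pass the stored
#' reference to transform held-out spectra identically.
#'
#' @param s A [spectrum_set()] with >= 2 channels.
#' @param reference `"mean"` or a numeric reference spectrum.
#' @return Corrected `spectrum_set`; the reference actually used is stored
#'   in the appended provenance record (`$reference`).
#' @export
msc <- function(s, reference = "mean") {
  stopifnot(inherits(s, "spectrum_set"))
  if (length(s$wavenumbers) < 2) stop("MSC needs at least 2 channels")
  ref <- if (identical(reference, "mean")) colMeans(s$intensities) else {
    stopifnot(is.numeric(reference), length(reference) == length(s$wavenumbers))
    as.numeric(reference)
  }
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  if (denom == 0) stop("degenerate MSC reference (constant)")
  # per-spectrum OLS slope b_i = <y_i - mean(y_i), ref - mean(ref)> / ||ref - mean(ref)||^2
  yc_mean <- rowMeans(s$intensities)
  b <- as.numeric((s$intensities - yc_mean) %*% rc) / denom
  if (any(b == 0)) stop("degenerate MSC fit (b = 0) for: ",
                        paste(s$sample_ids[b == 0], collapse = ", "))
  a <- yc_mean - b * mean(ref)
  s$intensities <- (s$intensities - a) / b
  append_provenance(s, "msc", list(reference = ref))
}

#' Savitzky-Golay derivative
#'
#' Per spectrum, the local-polynomial derivative with respect to channel
#' index (window of `window` points, polynomial of degree `order`,
#' `deriv`-th derivative), computed with the `signal` package's
#' Savitzky-Golay projection filter. The study setting is a 5-point,
#' 2nd-order, 1st-derivative filter.
#'
#' @param s A [spectrum_set()].
#' @param window Odd window length <= channel count.
#' @param order Polynomial degree < `window`.
#' @param deriv Derivative order.
#' @return Differentiated `spectrum_set`.
#' @export
savgol_derivative <- function(s, window = 5, order = 2, deriv = 1) {
  stopifnot(inherits(s, "spectrum_set"))
  if (window %% 2 == 0) stop("window must be odd")
  if (window > length(s$wavenumbers)) stop("window larger than channel count")
  if (order >= window) stop("polynomial order must be < window")
  s$intensities <- t(apply(s$intensities, 1, function(y)
    signal::sgolayfilt(y, p = order, n = window, m = deriv, ts = 1)))
  append_provenance(s, "savgol_derivative",
                    list(window = window, order = order, deriv = deriv))
}

#' Mean centering
#'
#' Subtracts column (channel) means. With `mean = "fit"` the means are
#' computed from this set (training) and stored in the provenance record;
#' pass a stored mean vector to centre held-out spectra identically.
#'
#' @param s A [spectrum_set()].
#' @param mean `"fit"` or a numeric vector of channel means.
#' @return Centred `spectrum_set`.
#' @export
mean_center <- function(s, mean = "fit") {
  stopifnot(inherits(s, "spectrum_set"))
  mu <- if (identical(mean, "fit")) colMeans(s$intensities) else {
    if (length(mean) != length(s$wavenumbers))
      stop("mean length (", length(mean), ") does not match channel count (",
           length(s$wavenumbers), ")")
    as.numeric(mean)
  }
  s$intensities <- sweep(s$intensities, 2, mu)
  append_provenance(s, "mean_center", list(mean = mu))
}

#' Standard pretreatment recipes
#'
#' The recipes used by the study, per modality: Raman spectra are cropped to
#' 350-1680 cm^-1, AsLS baseline corrected (p = 0.001, lambda = 1e4), SNV
#' normalised and mean centred; NIR spectra are cropped (transmission:
#' 7600-8000 and 8500-13000 cm^-1; reflection: 4200-7400 cm^-1),
#' differentiated (Savitzky-Golay, 5 points, 2nd order, 1st derivative),
#' MSC corrected and mean centred.
#'
#' @param modality One of the four modality tags.
#' @return A recipe: list of steps, each `list(op = <name>, ...params)`.
#' @export
default_recipe <- function(modality) {
  keep <- switch(modality,
    raman_trans = ,
    raman_refl  = list(c(350, 1680)),
    nir_trans   = list(c(7600, 8000), c(8500, 13000)),
    nir_refl    = list(c(4200, 7400)),
    stop("unknown modality: ", modality)
  )
  if (startsWith(modality, "raman")) {
    list(list(op = "exclude_regions", keep = keep),
         list(op = "asls_baseline", p = 0.001, lam = 1e4),
         list(op = "snv"),
         list(op = "mean_center"))
  } else {
    list(list(op = "exclude_regions", keep = keep),
         list(op = "savgol_derivative", window = 5, order = 2, deriv = 1),
         list(op = "msc"),
         list(op = "mean_center"))
  }
}

#' Apply a pretreatment recipe, optionally replaying fitted state
#'
#' Applies the recipe's operators in order. On a training set (no `state`),
#' data-dependent operators (MSC reference, column means) fit their state,
#' which is returned so the identical transform can be replayed on held-out
#' spectra.
#'
#' @param s A [spectrum_set()].
#' @param recipe A recipe as from [default_recipe()].
#' @param state Fitted state from a previous call, or `NULL` to fit.
#' @return `list(spectra = <spectrum_set>, state = <list>)`.
#' @export
apply_recipe <- function(s, recipe, state = NULL) {
  fitting <- is.null(state)
  if (fitting) state <- vector("list", length(recipe))
  for (i in seq_along(recipe)) {
    step <- recipe[[i]]
    s <- switch(step$op,
      exclude_regions = exclude_regions(s, step$keep),
      asls_baseline = asls_baseline(s, p = step$p %||% 0.001,
                                    lam = step$lam %||% 1e4),
      snv = snv(s),
      msc = if (fitting) msc(s, reference = step$reference %||% "mean")
            else msc(s, reference = state[[i]]$reference),
      savgol_derivative = savgol_derivative(s, window = step$window %||% 5,
                                            order = step$order %||% 2,
                                            deriv = step$deriv %||% 1),
      mean_center = if (fitting) mean_center(s, mean = "fit")
                    else mean_center(s, mean = state[[i]]$mean),
      stop("unknown recipe operator: ", step$op)
    )
    if (fitting) {
      last <- s$provenance[[length(s$provenance)]]
      state[[i]] <- last[setdiff(names(last), "op")]
    }
  }
  list(spectra = s, state = state)
}
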