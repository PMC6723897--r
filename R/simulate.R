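# Synthetic data generator: ground-truth dissolution kinetics and mixture
# spectra emulating the four-component matrix tablet study (DR drug, HPMC
# matrix polymer, MCC filler, MgSt lubricant) measured by NIR and Raman in
# transmission and reflection.

#' Simulator configuration
#'
#' Bundles every tunable of the synthetic data generator: between-tablet
#' composition/force noise, dissolution kinetics, per-modality pure-component
#' peak lists, baselines and noise models.
#'
#' Dissolution kinetics are a Weibull release curve
#' `D(t) = Dmax * (1 - exp(-(t/tau)^beta))` whose plateau scales with drug
#' load (`Dmax = 100 * dr / dr_ref`, profiles being expressed in % of the
#' reference 8 % dose) and whose time constant
#' `tau = tau0 * (1 + hill_A * h(hpmc)) * (force/force_ref)^force_exp`
#' carries a saturating Hill-type polymer retardation
#' `h(c) = c^n / (K^n + c^n)`: release is near-immediate at 10 % HPMC,
#' strongly retarded at 20 % and only marginally more so at 30 %, and
#' compression force has a weak effect concentrated on the early curve.
#'
#' Spectra are sums of Gaussian pure-component peaks weighted by the true
#' mass fractions, distorted by a per-sample multiplicative scatter factor,
#' a smooth additive baseline (a steep low-wavenumber fluorescence slope for
#' Raman), and additive Gaussian noise inflated inside configured noisy edge
#' regions and reduced by the square root of the number of averaged
#' replicate acquisitions per tablet (two for the Raman modalities, per the
#' emulated acquisition protocol). Reflection channels carry more noise and scatter than
#' transmission, so downstream calibrations rank transmission better.
#'
#' @param noise_scale Global multiplier on spectral additive noise and
#'   scatter spread (1 = study conditions; used for noise-floor studies).
#' @param composition_rel_sd Relative s.d. of true vs nominal composition
#'   (between-tablet content variability), default 2 %.
#' @param force_sd S.d. of measured vs set compression pressure, MPa.
#' @param profile_sd Additive s.d. of measured dissolution points, % released.
#' @param tablets_per_setting Tablets manufactured and analysed per setting.
#' @return A nested list of class `simulator_config`.
#' @export
simulator_config <- function(noise_scale = 1, composition_rel_sd = 0.02,
                             force_sd = 1, profile_sd = 1,
                             tablets_per_setting = 4L) {
  stopifnot(noise_scale >= 0, composition_rel_sd >= 0, force_sd >= 0,
            profile_sd >= 0, tablets_per_setting >= 1)
  peaks <- function(component, center, width, height) {
    stopifnot(all(width > 0), all(height >= 0))
    data.frame(component = component, center = center, width = width,
               height = height, stringsAsFactors = FALSE)
  }
  # Raman grid 200-1890 cm^-1 @ 4 cm^-1: narrow aromatic drug bands
  # (1645/1605/1560/1345 region) dominate. The two cellulosic excipients
  # (HPMC, MCC) share nearly the same skeletal bands around 1090-1120 cm^-1,
  # so the polymer-specific signal direction in Raman is weak - as for real
  # cellulose ethers vs microcrystalline cellulose.
  raman_peaks <- rbind(
    peaks("dr",   c(1645, 1605, 1560, 1345, 1230, 760), c(8, 8, 8, 10, 12, 10),
          c(1.0, 0.9, 0.7, 0.8, 0.5, 0.4)),
    peaks("hpmc", c(1090, 1120, 1380, 520, 435, 1460), c(14, 14, 16, 20, 18, 20),
          c(0.210, 0.168, 0.126, 0.101, 0.084, 0.015)),
    peaks("mcc",  c(1090, 1120, 1380, 520, 435), c(14, 14, 16, 20, 18),
          c(0.25, 0.20, 0.15, 0.12, 0.10)),
    peaks("mgst", c(1060, 1445, 1296), c(10, 12, 8), c(0.20, 0.25, 0.30))
  )
  # NIR 4000-15000 cm^-1: broad polymer overtone/combination bands (11000/
  # 10300/9800 and 8850/7750 regions) dominate; aromatic drug bands are
  # comparatively weak in NIR.
  nir_peaks <- rbind(
    peaks("hpmc", c(11000, 10300, 9800, 8850, 7750, 6900, 5800, 4800, 4400),
          c(150, 140, 130, 160, 140, 180, 150, 150, 120),
          c(0.50, 0.45, 0.40, 0.35, 0.30, 0.30, 0.35, 0.30, 0.25)),
    peaks("dr",   c(12500, 9500, 8800, 6600, 5900, 5100, 4600),
          c(120, 100, 90, 90, 80, 90, 80),
          c(0.05, 0.10, 0.12, 0.10, 0.09, 0.10, 0.08)),
    peaks("mcc",  c(10400, 8300, 7000, 6300, 5200, 4750, 4300),
          c(200, 180, 200, 180, 170, 160, 140),
          c(0.30, 0.25, 0.35, 0.30, 0.35, 0.30, 0.25)),
    peaks("mgst", c(8400, 5700, 4330), c(120, 120, 100), c(0.20, 0.20, 0.15))
  )
  raman_baseline <- list(kind = "fluorescence", amp = 6, decay = 250,
                         amp_rel_sd = 0.3, offset_sd = 0.3)
  nir_baseline <- list(kind = "linear", offset_sd = 0.3, slope_sd = 0.1,
                       mid = 9500, span = 5500)
  modalities <- list(
    raman_trans = list(grid = list(from = 200, to = 1890, by = 4),
                       peaks = raman_peaks, baseline = raman_baseline,
                       replicate_spectra = 2L,
                       scatter_sd = 0.03, noise_sd = 0.05,
                       noisy_edges = list(list(lo = 1680, hi = 1890, factor = 8))),
    raman_refl  = list(grid = list(from = 200, to = 1890, by = 4),
                       peaks = raman_peaks,
                       baseline = utils::modifyList(raman_baseline, list(amp = 10)),
                       replicate_spectra = 2L,
                       scatter_sd = 0.08, noise_sd = 0.15,
                       noisy_edges = list(list(lo = 1680, hi = 1890, factor = 8))),
    nir_trans   = list(grid = list(from = 4000, to = 15000, by = 32),
                       peaks = nir_peaks, baseline = nir_baseline,
                       scatter_sd = 0.03, noise_sd = 0.015,
                       noisy_edges = list(list(lo = 4000, hi = 7600, factor = 10),
                                          list(lo = 8000, hi = 8500, factor = 10),
                                          list(lo = 13000, hi = 15000, factor = 6))),
    nir_refl    = list(grid = list(from = 4000, to = 10000, by = 8),
                       peaks = nir_peaks, baseline = nir_baseline,
                       scatter_sd = 0.12, noise_sd = 0.25,
                       noisy_edges = list(list(lo = 4000, hi = 4200, factor = 8),
                                          list(lo = 7400, hi = 10000, factor = 8)))
  )
  structure(
    list(
      noise_scale = noise_scale,
      composition_rel_sd = composition_rel_sd,
      force_sd = force_sd,
      profile_sd = profile_sd,
      tablets_per_setting = as.integer(tablets_per_setting),
      mgst_pct = 1,
      kinetics = list(tau0 = 5, beta = 1, hill_K = 16, hill_n = 10,
                      hill_A = 55, dr_ref = 8, force_ref = 95.7,
                      force_exp = 0.15),
      modalities = modalities
    ),
    class = "simulator_config"
  )
}

#' Noise-free or noisy dissolution curve of one tablet
#'
#' Evaluates the simulator's Weibull release kinetics (see
#' [simulator_config()]) for a tablet of given true composition and
#' compression pressure over a time grid. With `noise = TRUE`, i.i.d.
#' Gaussian measurement noise (`profile_sd`) is added and the result is
#' clipped at 0.
#'
#' @param dr_true,hpmc_true True drug / polymer mass fractions, % w/w (> 0).
#' @param force Compression pressure, MPa (> 0).
#' @param times Strictly increasing sampling times, minutes.
#' @param config A [simulator_config()].
#' @param noise Add measurement noise?
#' @return Numeric vector of % released (of the reference 8 % dose), one per
#'   time point.
#' @export
simulate_profile <- function(dr_true, hpmc_true, force,
                             times = dissolution_time_grid(),
                             config = simulator_config(), noise = FALSE) {
  stopifnot(dr_true > 0, hpmc_true > 0, force > 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  k <- config$kinetics
  hill <- hpmc_true^k$hill_n / (k$hill_K^k$hill_n + hpmc_true^k$hill_n)
  tau <- k$tau0 * (1 + k$hill_A * hill) * (force / k$force_ref)^k$force_exp
  dmax <- 100 * dr_true / k$dr_ref
  d <- dmax * (1 - exp(-(times / tau)^k$beta))
  if (noise) d <- pmax(0, d + stats::rnorm(length(d), 0, config$profile_sd))
  d
}

# internal: pure-component spectrum matrix (component x channel)
pure_component_spectra <- function(grid, peak_table) {
  comps <- c("dr", "hpmc", "mcc", "mgst")
  s <- matrix(0, length(comps), length(grid), dimnames = list(comps, NULL))
  for (r in seq_len(nrow(peak_table))) {
    p <- peak_table[r, ]
    s[p$component, ] <- s[p$component, ] +
      p$height * exp(-0.5 * ((grid - p$center) / p$width)^2)
  }
  s
}

#' Simulate one modality's tablet spectra
#'
#' Mixture model: `intensity(sample, v) = m_s * sum_i c_i * s_i(v) + b_s(v)
#' + eps`, with pure-component spectra `s_i` built from the configured
#' Gaussian peak lists, per-sample multiplicative scatter `m_s`, a smooth
#' per-sample baseline `b_s`, and additive noise inflated inside the noisy
#' edge regions. Component mass fractions close to 100 %: MCC takes up the
#' remainder after DR, HPMC and 1 % MgSt.
#'
#' @param tablets Data frame with columns `tablet_id`, `dr_true`, `hpmc_true`.
#' @param modality One of `"nir_trans"`, `"nir_refl"`, `"raman_trans"`,
#'   `"raman_refl"`.
#' @param config A [simulator_config()].
#' @return A [spectrum_set()].
#' @export
simulate_spectra <- function(tablets, modality, config = simulator_config()) {
  if (!nrow(tablets)) stop("tablets must be nonempty")
  m <- config$modalities[[modality]]
  if (is.null(m)) stop("unknown modality: ", modality)
  grid <- seq(m$grid$from, m$grid$to, by = m$grid$by)
  pure <- pure_component_spectra(grid, m$peaks)
  conc <- cbind(dr = tablets$dr_true, hpmc = tablets$hpmc_true,
                mcc = 100 - tablets$dr_true - tablets$hpmc_true - config$mgst_pct,
                mgst = config$mgst_pct)
  n <- nrow(tablets)
  ideal <- conc %*% pure
  scatter <- exp(stats::rnorm(n, 0, m$scatter_sd * config$noise_scale))
  b <- m$baseline
  baseline <- if (identical(b$kind, "fluorescence")) {
    amp <- b$amp * exp(stats::rnorm(n, 0, b$amp_rel_sd))
    off <- stats::rnorm(n, 0, b$offset_sd)
    outer(amp, exp(-(grid - grid[1]) / b$decay)) + off
  } else {
    off <- stats::rnorm(n, 0, b$offset_sd)
    slp <- stats::rnorm(n, 0, b$slope_sd)
    off + outer(slp, (grid - b$mid) / b$span)
  }
  noise_sd <- rep(m$noise_sd, length(grid))
  for (e in m$noisy_edges)
    noise_sd[grid >= e$lo & grid <= e$hi] <- m$noise_sd * e$factor
  # replicate acquisitions per tablet are averaged before modelling: shot
  # noise shrinks by sqrt(r), while scatter and baseline are tablet
  # properties shared across replicates
  r_spec <- m$replicate_spectra %||% 1L
  eps <- matrix(stats::rnorm(n * length(grid)), n) *
    rep(noise_sd * config$noise_scale / sqrt(r_spec), each = n)
  spectrum_set(grid, scatter * ideal + baseline + eps,
               sample_ids = tablets$tablet_id, modality = modality)
}

#' Generate the full synthetic study dataset
#'
#' Draws the complete study: the 37-setting design, `tablets_per_setting`
#' tablets per setting (148 by default) with true compositions (nominal plus
#' between-tablet noise) and measured compression pressure, their noise-free
#' and measured 53-point dissolution profiles, and all four spectral
#' modalities. Fully reproducible: a fixed seed yields a bit-identical
#' dataset.
#'
#' @param config A [simulator_config()].
#' @param seed Integer RNG seed.
#' @return A list with elements `tablets` (data frame: `tablet_id`,
#'   `setting_id`, nominal/true compositions, `force` set, `force_measured`,
#'   `role`, `origin`), `times`, `profiles` (measured, tablets x 53),
#'   `profiles_true` (noise-free), `spectra` (named list of
#'   [spectrum_set()]s), `config` and `seed`.
#' @export
generate_dataset <- function(config = simulator_config(), seed = 1L) {
  set.seed(seed)
  design <- build_design()
  k <- config$tablets_per_setting
  tab <- design[rep(seq_len(nrow(design)), each = k), ]
  rownames(tab) <- NULL
  tab$tablet_id <- sprintf("S%02d_T%d", tab$setting_id, rep(seq_len(k), nrow(design)))
  n <- nrow(tab)
  tab$dr_true <- pmax(0.1, tab$dr_nominal *
                        (1 + stats::rnorm(n, 0, config$composition_rel_sd)))
  tab$hpmc_true <- pmax(0.1, tab$hpmc_nominal *
                          (1 + stats::rnorm(n, 0, config$composition_rel_sd)))
  tab$force_measured <- pmax(1, tab$force + stats::rnorm(n, 0, config$force_sd))
  tab <- tab[, c("tablet_id", "setting_id", "dr_nominal", "hpmc_nominal",
                 "dr_true", "hpmc_true", "force", "force_measured", "role",
                 "origin")]
  times <- dissolution_time_grid()
  profiles_true <- t(vapply(seq_len(n), function(i)
    simulate_profile(tab$dr_true[i], tab$hpmc_true[i], tab$force_measured[i],
                     times, config, noise = FALSE),
    numeric(length(times))))
  profiles <- pmax(profiles_true +
                     matrix(stats::rnorm(n * length(times), 0, config$profile_sd), n), 0)
  rownames(profiles_true) <- rownames(profiles) <- tab$tablet_id
  colnames(profiles_true) <- colnames(profiles) <- times
  spectra <- lapply(stats::setNames(nm = names(config$modalities)), function(mod)
    simulate_spectra(tab, mod, config))
  list(tablets = tab, times = times, profiles = profiles,
       profiles_true = profiles_true, spectra = spectra,
       config = config, seed = seed)
}
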