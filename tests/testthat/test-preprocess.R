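# Pretreatment operators: exactness properties, fitted-state replay on
# held-out data, and agreement of the sparse AsLS solver with an
# independent dense-matrix implementation.

test_that("region exclusion keeps exactly the requested windows, in order", {
  s <- as_specset(matrix(rnorm(3 * 200), 3), wn = seq(200, 1890, length.out = 200),
                  modality = "raman_trans")
  out <- exclude_regions(s, list(c(350, 1680)))
  expect_true(all(out$wavenumbers >= 350 & out$wavenumbers <= 1680))
  expect_true(all(diff(out$wavenumbers) > 0))
  # identity on the full range
  full <- exclude_regions(s, list(range(s$wavenumbers)))
  expect_equal(full$intensities, s$intensities, ignore_attr = TRUE)
  # disjoint windows leave a hole
  s2 <- as_specset(matrix(rnorm(2 * 300), 2), wn = seq(4000, 15000, length.out = 300),
                   modality = "nir_trans")
  out2 <- exclude_regions(s2, list(c(7600, 8000), c(8500, 13000)))
  expect_false(any(out2$wavenumbers > 8000 & out2$wavenumbers < 8500))
  expect_error(exclude_regions(s, list(c(5000, 6000))), "no channels retained")
})

test_that("AsLS removes smooth baselines while preserving narrow peaks", {
  x <- seq_len(200)
  baseline <- 5 + 0.03 * x - 1e-4 * x^2 + 2e-7 * x^3
  # constant spectrum collapses to zero
  s_const <- as_specset(matrix(rep(3, 150), 1))
  out <- asls_baseline(s_const, p = 0.001, lam = 1e4)
  expect_lt(max(abs(out$intensities)), 1e-6)
  # a smooth, slowly varying peakless curve (near-linear drift with gentle
  # undulation) is absorbed almost entirely
  drift <- 5 + 0.03 * x + 0.1 * sin(2 * pi * x / 400)
  s_smooth <- as_specset(matrix(drift, 1))
  out <- asls_baseline(s_smooth, p = 0.001, lam = 1e4)
  expect_lt(max(abs(out$intensities)), 0.01 * diff(range(drift)))
  # a narrow positive peak on the same baseline survives within 5 %
  peak <- 10 * exp(-0.5 * ((x - 100) / 4)^2)
  s_peak <- as_specset(matrix(baseline + peak, 1))
  out <- asls_baseline(s_peak, p = 0.001, lam = 1e4)
  expect_equal(max(out$intensities), 10, tolerance = 0.05)
  expect_error(asls_baseline(as_specset(matrix(1:2, 1))), "3 channels")
})

test_that("sparse AsLS agrees with an independent dense solver", {
  set.seed(4)
  x <- seq_len(180)
  spectra <- rbind(
    2 + 0.05 * x + 8 * exp(-0.5 * ((x - 60) / 3)^2),
    10 - 0.02 * x + 5 * exp(-0.5 * ((x - 120) / 5)^2) + rnorm(180, 0, 0.05)
  )
  # dense oracle: same penalised least squares, base-R linear algebra only
  dense_asls <- function(y, p, lam, max_iter = 50) {
    n <- length(y)
    D <- diff(diag(n), differences = 2)
    P <- lam * t(D) %*% D
    w <- rep(1, n)
    for (i in seq_len(max_iter)) {
      z <- solve(diag(w) + P, w * y)
      w_new <- ifelse(y > z, p, 1 - p)
      if (all(w_new == w)) break
      w <- w_new
    }
    y - z
  }
  out <- asls_baseline(as_specset(spectra), p = 0.001, lam = 1e4)
  for (i in 1:2)
    expect_equal(out$intensities[i, ], dense_asls(spectra[i, ], 0.001, 1e4),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("SNV standardises each spectrum; zero variance is an error", {
  s <- as_specset(rbind(c(1, 2, 3), c(10, 20, 60)))
  out <- snv(s)
  expect_equal(out$intensities[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(unname(rowMeans(out$intensities)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(out$intensities, 1, sd)), c(1, 1), tolerance = 1e-12)
  # SNV is a fixed point on already-normalised spectra
  out2 <- snv(out)
  expect_equal(out2$intensities, out$intensities, tolerance = 1e-12)
  s_bad <- as_specset(rbind(c(1, 2, 3), c(5, 5, 5)), modality = "m")
  expect_error(snv(s_bad), "s2")   # offending sample named
})

test_that("MSC inverts additive/multiplicative distortion against the reference", {
  ref <- sin(seq(0, 3, length.out = 80)) + 2
  s <- as_specset(rbind(ref, 2 * ref + 3))
  out <- msc(s, reference = ref)
  expect_equal(out$intensities[1, ], ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(out$intensities[2, ], ref, tolerance = 1e-12, ignore_attr = TRUE)
  # the reference used is stored for replay on held-out data
  prov <- out$provenance[[length(out$provenance)]]
  expect_equal(prov$reference, ref, ignore_attr = TRUE)
})

test_that("Savitzky-Golay derivative is exact on low-order polynomials", {
  i <- seq_len(60)
  lin <- as_specset(matrix(2 * i, 1))
  expect_equal(savgol_derivative(lin, 5, 2, 1)$intensities[1, ],
               rep(2, 60), tolerance = 1e-10, ignore_attr = TRUE)
  quad <- as_specset(matrix(i^2, 1))
  expect_equal(savgol_derivative(quad, 5, 2, 1)$intensities[1, ],
               2 * i, tolerance = 1e-8, ignore_attr = TRUE)
  const <- as_specset(matrix(rep(7, 60), 1))
  expect_equal(max(abs(savgol_derivative(const)$intensities)), 0, tolerance = 1e-12)
  expect_error(savgol_derivative(lin, window = 4), "odd")
  expect_error(savgol_derivative(lin, window = 61), "larger")
})

test_that("mean centering fits on training data and replays on held-out data", {
  set.seed(2)
  s <- as_specset(matrix(rnorm(5 * 30, mean = 3), 5))
  out <- mean_center(s)
  expect_lt(max(abs(colMeans(out$intensities))), 1e-12)
  # idempotent when refit
  out2 <- mean_center(out)
  expect_equal(out2$intensities, out$intensities, tolerance = 1e-12)
  # stored means applied to different data leave nonzero column means
  mu <- out$provenance[[length(out$provenance)]]$mean
  s_test <- as_specset(matrix(rnorm(4 * 30, mean = 5), 4))
  out_test <- mean_center(s_test, mean = mu)
  expect_gt(max(abs(colMeans(out_test$intensities))), 0.1)
  expect_error(mean_center(s, mean = 1:3), "does not match")
})

test_that("recipes replay the fitted transform exactly on held-out spectra", {
  ds <- small_dataset()
  train <- ds$tablets$role == "train"
  s_all <- ds$spectra$nir_trans
  fitted <- apply_recipe(subset_specset(s_all, train), default_recipe("nir_trans"))
  # replaying the state on the training set itself reproduces the output
  replay <- apply_recipe(subset_specset(s_all, train),
                         default_recipe("nir_trans"), state = fitted$state)
  expect_equal(replay$spectra$intensities, fitted$spectra$intensities,
               tolerance = 1e-12)
  # held-out spectra are transformed with the *training* reference/means:
  # their column means need not vanish
  test_out <- apply_recipe(subset_specset(s_all, !train),
                           default_recipe("nir_trans"), state = fitted$state)
  expect_gt(max(abs(colMeans(test_out$spectra$intensities))), 1e-6)
  expect_equal(test_out$spectra$wavenumbers, fitted$spectra$wavenumbers)
  # provenance names every applied operator in order
  ops <- vapply(fitted$spectra$provenance, function(p) p$op, character(1))
  expect_equal(ops, c("exclude_regions", "savgol_derivative", "msc", "mean_center"))
  # empty recipe is the identity
  id <- apply_recipe(s_all, list())
  expect_equal(id$spectra$intensities, s_all$intensities)
})
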