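# f2 similarity analytics, profile RMSEP, DR normalisation and the
# factorial standardized-effects analysis (with a normal-equations oracle
# and a planted-effect power check).

test_that("f2 takes its closed-form values on uniform deviations", {
  set.seed(40)
  R <- simulate_profile(8, 20, 95.7)
  expect_equal(f2_similarity(R, R), 100, tolerance = 1e-12)
  expect_equal(f2_similarity(R, R + sqrt(99)), 50, tolerance = 1e-9)
  expect_equal(f2_similarity(R, R + 10), 49.89, tolerance = 0.01)
  for (d in c(1, 5, 10, 20))
    expect_equal(f2_similarity(R, R + d),
                 50 * log10(100 / sqrt(1 + d^2)), tolerance = 1e-9)
  expect_error(f2_similarity(R, R[-1]), "mismatch")
})

test_that("f2 is symmetric under unit weights and decreases with deviation", {
  set.seed(41)
  R <- simulate_profile(8, 20, 95.7)
  T1 <- R + rnorm(53, 0, 3)
  expect_equal(f2_similarity(R, T1), f2_similarity(T1, R), tolerance = 1e-12)
  # strictly decreasing when any single deviation grows
  T2 <- T1; T2[10] <- T2[10] + 5
  expect_lt(f2_similarity(R, T2), f2_similarity(R, T1))
  # weights shift the emphasis
  w <- rep(1, 53); w[1:7] <- 3
  expect_false(isTRUE(all.equal(f2_similarity(R, T1, w), f2_similarity(R, T1))))
  # truncation drops post-85 % points
  expect_gt(f2_similarity(R, R + 10 * (seq_len(53) > 20), truncate_85 = TRUE),
            f2_similarity(R, R + 10 * (seq_len(53) > 20)))
})

test_that("profile RMSEP matches hand arithmetic", {
  expect_equal(profile_rmsep(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(profile_rmsep(c(10, 20, 30), c(15, 25, 35)), 5)
  R <- c(0, 10, 50, 90); T <- c(1, 12, 47, 95)
  expect_equal(profile_rmsep(R, T), sqrt(mean(c(1, 4, 9, 25))), tolerance = 1e-12)
  expect_error(profile_rmsep(1:3, 1:4), "mismatch")
})

test_that("DR normalisation rescales to the 8 % reference", {
  p <- c(20, 60, 100)
  expect_equal(normalize_to_mean_dr(p, 8), p)
  expect_equal(normalize_to_mean_dr(100, 10), 80)
  expect_equal(normalize_to_mean_dr(60, 6), 80)
  expect_error(normalize_to_mean_dr(p, 0), "positive")
})

test_that("effects analysis on an orthogonal design matches the normal-equations oracle", {
  ds <- small_dataset()
  eff <- effects_analysis(ds$tablets, ds$profiles, ds$times, response_time = 15)
  expect_equal(nrow(eff), 10)
  # oracle: explicit model matrix + normal equations on the same rows
  fact <- ds$tablets$origin == "factorial"
  tab <- ds$tablets[fact, ]
  y <- ds$profiles[fact, match(15, ds$times)] * 8 / tab$dr_true
  d <- (tab$dr_nominal - 8) / 2
  h <- (tab$hpmc_nominal - 20) / 10
  f <- (tab$force - 95.7) / 31.9
  M <- cbind(1, d, h, f, d^2, h^2, f^2, d * h, d * f, h * f)
  beta <- solve(crossprod(M), crossprod(M, y))
  est <- eff$estimate[match(c("(Intercept)", "dr", "hpmc", "force",
                              "I(dr^2)", "I(hpmc^2)", "I(force^2)",
                              "dr:hpmc", "dr:force", "hpmc:force"), eff$term)]
  expect_equal(est, as.numeric(beta), tolerance = 1e-9)
  # the polymer's linear and quadratic terms dominate the early-curve response
  top2 <- eff$term[1:2]
  expect_setequal(top2, c("hpmc", "I(hpmc^2)"))
})

test_that("a pure linear response yields only that coefficient on the coded design", {
  ds <- small_dataset()
  fact <- ds$tablets$origin == "factorial"
  tab <- ds$tablets
  profiles <- ds$profiles
  # plant a response linear in the HPMC code, in %-released units, and undo
  # the DR normalisation the analysis applies
  h_code <- (tab$hpmc_nominal - 20) / 10
  planted <- 30 + 7 * h_code
  profiles[, match(960, ds$times)] <- planted * tab$dr_true / 8
  eff <- effects_analysis(tab, profiles, ds$times, response_time = 960)
  est <- setNames(eff$estimate, eff$term)
  expect_equal(unname(est["hpmc"]), 7, tolerance = 1e-8)
  expect_equal(unname(est["(Intercept)"]), 30, tolerance = 1e-8)
  others <- setdiff(eff$term, c("hpmc", "(Intercept)"))
  expect_lt(max(abs(est[others])), 1e-8)
})

test_that("a planted quadratic polymer effect is detected with high power", {
  ds <- small_dataset()
  tab <- ds$tablets
  fact <- tab$origin == "factorial"
  h_code <- (tab$hpmc_nominal - 20) / 10
  hits <- vapply(1:100, function(i) {
    profiles <- ds$profiles
    planted <- 40 + 12 * h_code^2 + rnorm(nrow(tab), 0, 2)
    profiles[, match(960, ds$times)] <- planted * tab$dr_true / 8
    eff <- effects_analysis(tab, profiles, ds$times, response_time = 960)
    eff$significant[eff$term == "I(hpmc^2)"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("effects analysis demands the complete factorial block", {
  ds <- small_dataset()
  broken <- ds$tablets
  broken <- broken[!(broken$setting_id == 5), ]
  expect_error(effects_analysis(broken, ds$profiles[ds$tablets$setting_id != 5, ],
                                ds$times), "factorial")
})

test_that("f2 reports aggregate per-tablet values and compare cleanly", {
  set.seed(42)
  ref <- t(vapply(1:4, function(i) simulate_profile(8, 20, 95.7), numeric(53)))
  pred <- ref + matrix(rnorm(4 * 53, 0, 3), 4)
  rep1 <- f2_report(pred, ref, paste0("t", 1:4), model = "A")
  expect_equal(rep1$mean_f2, mean(rep1$per_tablet$f2), tolerance = 1e-12)
  expect_true(all(rep1$per_tablet$f2 <= 100))
  rep2 <- f2_report(ref, ref, paste0("t", 1:4), model = "B")
  cmp <- compare_models(rep2, rep1)
  expect_equal(cmp$mean_f2[cmp$model == "B"], 100)
  expect_equal(cmp$diff_vs_other[1], -cmp$diff_vs_other[2])
  cmp_same <- compare_models(rep1, rep1)
  expect_equal(cmp_same$diff_vs_other, c(0, 0))
  rep3 <- f2_report(pred[1:3, ], ref[1:3, ], paste0("x", 1:3), model = "C")
  expect_error(compare_models(rep1, rep3), "mismatch")
})
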