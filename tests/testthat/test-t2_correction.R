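test_that("linear calibration: degenerate grids, sign, and B1 sensitivity", {
  expect_error(calibrate_linear(tissue_pools("phantom"), std_pulse(),
                                t2_grid = 100, t2_ref = 100),
               "degenerate")
  # water-only background: signal rises with T2, so k > 0
  m <- calibrate_linear(tissue_pools("phantom"), std_pulse(), t2_ref = 100)
  expect_gt(m$k, 0)
  expect_gt(m$calib$linear_r2, 0.99)
  # doubling B1 changes the spillover sensitivity
  m4 <- calibrate_linear(tissue_pools("phantom"), saturation_pulse(4, 2, 1.2),
                         t2_ref = 100)
  expect_gt(abs(m4$k - m$k) / abs(m$k), 0.1)
})

test_that("analytic background contribution is anchored, quadratic, monotone", {
  m <- brain_model()
  expect_equal(background_mtr_contribution(m, 0), 0)
  dT2 <- seq(-10, 10, 0.5)
  y <- background_mtr_contribution(m, dT2)
  fit <- lm(y ~ dT2 + I(dT2^2))
  expect_lt(max(abs(resid(fit))), 1e-3)
  expect_true(all(diff(y) > 0))
  expect_error(background_mtr_contribution(correction_model(), 1),
               "not calibrated")
})

test_that("quadratic calibration reproduces its own grid and the analytics", {
  m <- brain_model()
  expect_lt(m$calib$quad_residual, 1e-3)
  dT2 <- m$calib$t2_grid - m$t2_ref
  # the fitted polynomial tracks the analytic scaled-down curve
  fitted <- m$a * dT2^2 + m$b * dT2 + m$c
  ana <- background_mtr_contribution(m, dT2)
  expect_lt(max(abs(fitted - ana)), 1e-3)
  # decreasing T2 -> negative background contribution (underestimation)
  expect_lt(m$a * 25 - m$b * 5, 0)
  expect_gt(m$b, 0)
})

test_that("analytic-mode quadratic fit of a pure quadratic has no residual", {
  m <- brain_model()
  m2 <- calibrate_quadratic(tissue_pools("brain", 10), std_pulse(),
                            t2_ref = m$t2_ref, mode = "analytic", model = m)
  expect_lt(m2$calib$quad_residual, 1e-12)
  expect_equal(m2$a, m$scale * m$k^2, tolerance = 1e-6)
  expect_equal(m2$b, m$scale * 2 * m$s0 * m$k, tolerance = 1e-6)
})

test_that("corrections are exact identities when T2 never moves", {
  m <- brain_model()
  s <- dge_series(1:12, 0.3 + 0.001 * (1:12), 1:4,
                  mtr_asym = 0.01 + 1e-4 * (1:12))
  t2flat <- dynamic_t2(1:12, rep(44.3, 12), 1:4)
  s <- correct_single_offset(s, t2flat, m)
  expect_identical(s$dge_corrected, s$dge)
  s <- correct_mtr_asym(s, t2flat, m)
  expect_identical(s$dge_asym_corrected, s$dge_asym)
})

test_that("misaligned time axes and missing coefficients are rejected", {
  m <- brain_model()
  s <- single_offset_dge(dge_series(seq(0, 45 * 9, 45), rep(0.3, 10), 1:3))
  bad <- dynamic_t2(seq(0, 45 * 9, 45) + 30, rep(44, 10), 1:3)
  expect_error(correct_single_offset(s, bad, m), "misaligned")
  good <- dynamic_t2(seq(0, 45 * 9, 45) + 10, rep(44, 10), 1:3)
  expect_silent(correct_single_offset(s, good, m))
  expect_error(correct_single_offset(s, good, correction_model(a = 1, b = 1, c = 0)),
               "no linear coefficient")
  expect_error(correct_mtr_asym(mtr_asym_dge(dge_series(1:5, rep(1, 5), 1:2,
                                                        mtr_asym = rep(0, 5))),
                                dynamic_t2(1:5, rep(44, 5), 1:2),
                                correction_model(k = 1)),
               "no quadratic")
  # missing delta T2 flags the timepoint instead of crashing
  holey <- dynamic_t2(seq(0, 45 * 9, 45), c(rep(44, 9), NA), 1:3)
  sh <- correct_single_offset(s, holey, m)
  expect_true(is.na(sh$dge_corrected[10]) && !anyNA(sh$dge_corrected[-10]))
})

test_that("null experiment: T2 ramp with constant glucose is suppressed", {
  proto <- short_proto()
  sim <- simulate_dge_experiment(proto, "tumor", seed = 3,
                                 t2_coupling = "only",
                                 glucose_const = tumor_plateau())
  s <- truth_series(sim, proto)
  t2 <- truth_t2(sim, proto)
  m <- tumor_model_static()
  s <- correct_mtr_asym(correct_single_offset(s, t2, m), t2, m)
  post <- (proto$n_baseline + 1):proto$n_frames
  # uncorrected artifact is substantial; corrected is < 10% of it and < 0.1%
  expect_gt(mean(s$dge[post]), 1)
  expect_lt(abs(mean(s$dge_corrected[post])) / abs(mean(s$dge[post])), 0.1)
  expect_lt(abs(mean(s$dge_corrected[post])), 0.1)
  expect_gt(abs(mean(s$dge_asym[post])), 0.01)
  expect_lt(abs(mean(s$dge_asym_corrected[post])) / abs(mean(s$dge_asym[post])), 0.1)
  expect_lt(abs(mean(s$dge_asym_corrected[post])), 0.1)
})

test_that("combined experiment: bias directions and corrected plateaus", {
  proto <- short_proto()
  simC <- simulate_dge_experiment(proto, "tumor", seed = 4)
  simG <- simulate_dge_experiment(proto, "tumor", seed = 5, t2_coupling = FALSE)
  sC <- truth_series(simC, proto); sG <- truth_series(simG, proto)
  t2 <- truth_t2(simC, proto)
  m <- tumor_model_combined()
  sC <- correct_mtr_asym(correct_single_offset(sC, t2, m), t2, m)
  plat <- (proto$n_frames - 5):proto$n_frames
  ref_so <- mean(sG$dge[plat]); ref_ma <- mean(sG$dge_asym[plat])
  # T2 drop inflates single-offset DGE and deflates MTR_asym DGE
  expect_gt(mean(sC$dge[plat]), ref_so)
  expect_lt(mean(sC$dge_asym[plat]), ref_ma)
  # correction moves both toward the glucose-only reference, within 10%
  expect_lt(abs(mean(sC$dge_corrected[plat]) - ref_so) / ref_so, 0.1)
  expect_lt(abs(mean(sC$dge_asym_corrected[plat]) - ref_ma) / abs(ref_ma), 0.1)
})

test_that("decoupling report: exact, null, and simulated correlations", {
  # exact proportionality
  tt <- 1:10
  s <- dge_series(tt, rep(0.3, 10), 1:3)
  s$dge <- 2 * (40 + tt)
  t2 <- dynamic_t2(tt, 40 + tt, 1:3)
  rep1 <- decoupling_report(s, t2)
  expect_equal(rep1$r[rep1$metric == "single_offset"], 1, tolerance = 1e-12)
  # constant series flagged, not crashed
  s$dge <- rep(1, 10)
  rep2 <- decoupling_report(s, t2)
  expect_true(is.na(rep2$r[1]) && rep2$flag[1] == "constant-series")
  # independent noise: |R| < 0.3 in at least 95% of seeds at n = 100
  set.seed(424242)
  hits <- sum(replicate(50, {
    sx <- dge_series(1:100, rep(0.3, 100), 1:10)
    sx$dge <- rnorm(100)
    tx <- dynamic_t2(1:100, 44 + rnorm(100), 1:10)
    abs(decoupling_report(sx, tx)$r[1]) < 0.3
  }))
  expect_gte(hits, 48)
})

test_that("correction model JSON round trip is bit-exact", {
  m <- brain_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_correction_model(m, path)
  m2 <- read_correction_model(path)
  for (f in c("k", "a", "b", "c", "t2_ref", "s0", "scale"))
    expect_identical(m2[[f]], m[[f]])
})
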