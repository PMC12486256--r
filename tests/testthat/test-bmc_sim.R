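test_that("tilt angle follows the effective-field geometry", {
  # on-resonance -> pi/2; equal components -> pi/4; far off-resonance -> 0
  expect_equal(tilt_angle(std_pulse(offset = 0)), pi / 2)
  p <- std_pulse(offset = 1.2)
  w1_ppm <- p$omega1 / (p$gamma * p$b0 * 1e-6)
  expect_equal(tilt_angle(std_pulse(offset = w1_ppm)), pi / 4)
  expect_lt(tilt_angle(std_pulse(offset = 500)), 1e-3)
  expect_error(tilt_angle(saturation_pulse(0, 2, 0)), "undefined")
})

test_that("effective rotating-frame rate interpolates between R1 and R2", {
  expect_equal(r_eff(1, 14, 0), 1)
  expect_equal(r_eff(1, 14, pi / 2), 14)
  expect_equal(r_eff(1, 14, pi / 4), 7.5)
  for (th in seq(0, pi / 2, length.out = 7)) {
    v <- r_eff(0.5, 22, th)
    expect_gte(v, 0.5); expect_lte(v, 22)
  }
  expect_error(r_eff(-1, 14, 0.3), "must be > 0")
})

test_that("glucose relaxivity relation and defaults", {
  expect_equal(glucose_r2(0, 14), 14)
  expect_equal(glucose_r2(10, 14), 14.53)
  expect_equal(formals(glucose_r2)$r2ex, 0.053)
  expect_error(glucose_r2(-5, 14), "must be >= 0")
  # ms-domain helper is the exact inverse
  expect_equal(glucose_r2(31.6, 1000 / 47.5), 1000 / glucose_t2_ms(31.6, 47.5))
})

test_that("steady-state R1rho signal matches the numeric propagator", {
  pools <- two_pool(20)
  offs <- seq(-5, 5, 0.25)
  offs <- offs[abs(offs) >= 0.5 - 1e-9]
  long <- saturation_pulse(2, 30, 1.2)
  zn <- bmc_propagate(pools, long, offs)
  za <- vapply(offs, function(o)
    steady_state_signal(pools, pulse_at_offset(long, o))$s_ss, numeric(1))
  expect_lt(max(abs(zn$signal - za) / za), 0.01)
  # no solutes, nearly longitudinal effective field -> no saturation
  far <- steady_state_signal(list(water_pool(1.8, 0.0443)),
                             std_pulse(offset = 200))
  expect_gt(far$s_ss, 0.999)
  # on-resonance: cos^2(theta) = 0
  expect_equal(steady_state_signal(list(water_pool(1.8, 0.0443)),
                                   std_pulse(offset = 0))$s_ss, 0)
  expect_error(steady_state_signal(list(), std_pulse()), "empty")
})

test_that("response components satisfy r1rho = r_eff + r_st", {
  resp <- steady_state_signal(two_pool(50), std_pulse())
  expect_equal(resp$r1rho, resp$r_eff + resp$r_st)
  expect_gt(resp$r_st, 0)
  expect_true(resp$s_ss >= 0 && resp$s_ss <= 1)
})

test_that("spillover-dominant approximation is linear in T2", {
  t2s <- c(40, 44, 48)
  s <- vapply(t2s, function(t2) {
    steady_state_signal(list(water_pool(1.8, t2 / 1000)), std_pulse(),
                        spillover_approx = TRUE)$s_ss
  }, numeric(1))
  slopes <- diff(s) / diff(t2s)
  expect_equal(slopes[1], slopes[2], tolerance = 1e-9)
})

test_that("transient signal approaches steady state at rate R1rho", {
  pools <- two_pool(20)
  r1rho <- steady_state_signal(pools, std_pulse())$r1rho
  # t_sat -> 0: the projected initial condition cos^2(theta)
  t0 <- transient_signal(pools, std_pulse(t_sat = 1e-9))
  expect_equal(t0$s_t, cos(t0$theta)^2, tolerance = 1e-6)
  # exponential settling in the weak-saturation regime
  weak <- pulse_at_offset(std_pulse(), 3)
  rw <- steady_state_signal(pools, weak)$r1rho
  ts <- transient_signal(pools, saturation_pulse(2, 5 / rw, 3))
  expect_lt(abs(ts$s_t - ts$s_ss) / ts$s_ss, 0.01)
  # mid-course agreement with the numeric propagator
  mid <- saturation_pulse(2, 1 / r1rho, 1.2)
  st <- transient_signal(pools, mid)$s_t
  sb <- bmc_propagate(pools, mid, 1.2)$signal
  expect_lt(abs(st - sb) / sb, 0.02)
  expect_error(transient_signal(pools, saturation_pulse(2, -1, 1.2)),
               "t_sat")
})

test_that("propagator limits: no irradiation and water-only symmetry", {
  w <- list(water_pool(1.8, 0.0443))
  offs <- seq(-3, 3, 0.5)
  z0 <- bmc_propagate(w, saturation_pulse(0, 2, 1.2), offs)
  expect_equal(z0$signal, rep(1, length(offs)), tolerance = 1e-12)
  zs <- bmc_propagate(w, std_pulse(), seq(-5, 5, 0.1))
  expect_lt(max(abs(zs$signal - rev(zs$signal))), 1e-12)
})

test_that("signal at +1.2 ppm is strictly monotone in glucose and in T2", {
  concs <- seq(0, 500, 50)
  s <- vapply(concs, function(cc)
    bmc_propagate(two_pool(cc), std_pulse(), 1.2)$signal, numeric(1))
  expect_true(all(diff(s) < 0))
  t2s <- seq(20, 100, 10)
  sT <- vapply(t2s, function(t2)
    bmc_propagate(two_pool(50, t2), std_pulse(), 1.2)$signal, numeric(1))
  expect_true(all(diff(sT) > 0))
})

test_that("glucose response is near-linear over 0-100 mM", {
  concs <- seq(0, 100, 10)
  res <- vapply(concs, function(cc) {
    z <- bmc_propagate(two_pool(cc), std_pulse(), c(-1.2, 1.2))
    c(s = z$signal[2], ma = z$signal[1] - z$signal[2])
  }, numeric(2))
  expect_gt(summary(lm(res["s", ] ~ concs))$r.squared, 0.99)
  expect_gt(summary(lm(res["ma", ] ~ concs))$r.squared, 0.99)
  expect_lt(coef(lm(res["s", ] ~ concs))[2], 0)
  expect_gt(coef(lm(res["ma", ] ~ concs))[2], 0)
})

test_that("saturation-transfer rates are additive across dilute pools", {
  w <- water_pool(1.8, 0.0443)
  glc <- exchange_pool("glucose", 1.2, glucose_fraction(20), 4000, 1, 0.015)
  amide <- exchange_pool("amide", 3.5, 0.002, 50, 1.1, 0.02)
  est_rst <- function(pools) {
    long <- saturation_pulse(2, 30, 1.2)
    s <- bmc_propagate(pools, long, 1.2)$signal
    th <- tilt_angle(long)
    cos(th)^2 * w$r1 / s - r_eff(w$r1, w$r2, th)
  }
  lone <- est_rst(list(w, glc)) + est_rst(list(w, amide))
  both <- est_rst(list(w, glc, amide))
  expect_lt(abs(both - lone) / lone, 0.01)
  # analytic r_st sums by construction and stays close to the numeric value
  expect_lt(abs(r_st(list(w, glc, amide), std_pulse()) - both) / both, 0.05)
})

test_that("pool and pulse validation rejects unphysical input", {
  expect_error(exchange_pool("x", 1, -0.1, 10, 1, 1), "fraction")
  expect_error(exchange_pool("x", 1, 0.1, -1, 1, 1), "k_ex")
  expect_error(exchange_pool("x", 1, 0.1, 10, 0, 1), "t1 and t2")
  expect_error(pool_system(list(two_pool()[[2]])), "exactly one water")
  expect_error(saturation_pulse(-1, 2), "b1")
  expect_error(saturation_pulse(2, 0), "t_sat")
  expect_error(z_spectrum(c(1, 1, 2), c(0.1, 0.2, 0.3)), "monotone")
})
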