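noiseless_stack <- function(t2s, pd = 1000, et = echo_train()) {
  n <- length(t2s)
  img <- array(NA_real_, c(n, 1, et$n_echoes))
  for (i in seq_len(n)) img[i, 1, ] <- pd * exp(-et$te_eff / t2s[i])
  multi_echo_stack(img, et)
}

test_that("noiseless mono-exponential recovery is exact across T2 range", {
  t2s <- c(20, 44.3, 77, 120)
  for (method in c("nonlinear", "loglinear")) {
    maps <- fit_t2_pd(noiseless_stack(t2s), method = method)
    expect_lt(max(abs(maps$t2[, 1] - t2s) / t2s), 1e-6)
    expect_lt(max(abs(maps$pd[, 1] - 1000) / 1000), 1e-6)
    expect_true(all(maps$fit_quality[, 1] > 0.999))
  }
})

test_that("two-echo fit reproduces the closed form", {
  et <- echo_train(2, 25)
  s1 <- 800; s2 <- 445
  img <- array(rep(c(s1, s2), each = 4), c(2, 2, 2))
  maps <- fit_t2_pd(multi_echo_stack(img, et))
  expect_equal(maps$t2[1, 1], 25 / log(s1 / s2), tolerance = 1e-8)
})

test_that("Rician noise at SNR 50 leaves median T2 bias under 3%", {
  set.seed(20240811)
  n <- 10000; t2 <- 50; pd <- 1000; et <- echo_train()
  sigma <- pd / 50
  clean <- outer(rep(pd, n), exp(-et$te_eff / t2))
  noisy <- sqrt((clean + matrix(rnorm(n * 5, 0, sigma), n))^2 +
                  matrix(rnorm(n * 5, 0, sigma), n)^2)
  maps <- fit_t2_pd(multi_echo_stack(array(noisy, c(n, 1, 5)), et))
  expect_lt(abs(median(maps$t2, na.rm = TRUE) - t2) / t2, 0.03)
  # and median absolute error under 5%
  expect_lt(median(abs(maps$t2 - t2), na.rm = TRUE) / t2, 0.05)
})

test_that("PD estimates do not leak T2 variation", {
  # constant PD, T2 sweeping the physiological range, mild noise; the PD map
  # must stay flat and uncorrelated with the T2 map
  set.seed(5150)
  n <- 20000; et <- echo_train()
  t2s <- seq(25, 120, length.out = n)
  clean <- 1000 * exp(-outer(1 / t2s, et$te_eff))
  sigma <- 1000 / 100
  noisy <- sqrt((clean + matrix(rnorm(5 * n, 0, sigma), n))^2 +
                  matrix(rnorm(5 * n, 0, sigma), n)^2)
  maps <- fit_t2_pd(multi_echo_stack(array(noisy, c(n, 1, 5)), et))
  ok <- maps$mask[, 1]
  expect_lt(summary(lm(maps$pd[ok, 1] ~ maps$t2[ok, 1]))$r.squared, 0.001)
  # noiseless: the PD map is flat to well under 1% despite the T2 sweep
  flat <- fit_t2_pd(noiseless_stack(seq(25, 120, length.out = 32)))
  expect_lt(sd(flat$pd[, 1]) / mean(flat$pd[, 1]), 0.01)
})

test_that("dropping the last echo does not move noiseless estimates", {
  t2s <- c(30, 44.3, 90)
  full <- fit_t2_pd(noiseless_stack(t2s))
  et4 <- echo_train(4, 25)
  img4 <- noiseless_stack(t2s)$data[, , 1:4, drop = FALSE]
  four <- fit_t2_pd(multi_echo_stack(img4, et4))
  expect_lt(max(abs(full$t2 - four$t2) / full$t2), 1e-6)
})

test_that("voxels below the noise floor or with short data are flagged", {
  et <- echo_train()
  img <- array(1000 * exp(-rep(et$te_eff, each = 4) / 50), c(2, 2, 5))
  img[2, 2, ] <- 1          # noise-floor voxel
  maps <- fit_t2_pd(multi_echo_stack(img, et))
  expect_false(maps$mask[2, 2])
  expect_true(is.na(maps$t2[2, 2]))
  expect_true(all(maps$mask[1:2, 1], maps$mask[1, 2]))
  all_bad <- multi_echo_stack(array(0, c(2, 2, 5)), et)
  expect_error(fit_t2_pd(all_bad), "no valid voxels")
})

test_that("PD Z-spectrum normalization behaves as a ratio", {
  et <- echo_train()
  base <- noiseless_stack(c(40, 60, 80))
  unsat <- fit_t2_pd(base)
  # identical maps -> flat unity spectrum
  flat <- pd_zspectrum(list(unsat, unsat, unsat), unsat, c(-1, 0, 1),
                       roi = matrix(TRUE, 3, 1))
  expect_equal(flat$signal, rep(1, 3), tolerance = 1e-12)
  # scaled PD -> the scale factor
  scaled <- fit_t2_pd(multi_echo_stack(base$data * 0.8, et))
  z <- pd_zspectrum(list(scaled), unsat, 1.2, roi = matrix(TRUE, 3, 1))
  expect_equal(z$signal, 0.8, tolerance = 1e-9)
  # voxel-wise mode returns per-voxel ratios
  arr <- pd_zspectrum(list(scaled), unsat, 1.2)
  expect_equal(dim(arr), c(3, 1, 1))
  expect_equal(unname(arr[1, 1, 1]), 0.8, tolerance = 1e-9)
})

test_that("FWHM of an ideal Lorentzian dip recovers its analytic width", {
  off <- seq(-5, 5, 0.1)
  for (gam in c(0.6, 1.1)) {
    z <- z_spectrum(off, 1 - 0.8 * gam^2 / (gam^2 + off^2))
    expect_equal(spectrum_fwhm(z), 2 * gam, tolerance = 0.05)
  }
  expect_error(spectrum_fwhm(z_spectrum(off, rep(0.9, length(off)))),
               "FWHM undefined")
  expect_error(spectrum_fwhm(z_spectrum(off, seq(0, 1, length.out = length(off)))),
               "FWHM undefined")
})

test_that("water-line narrowing: doubling T2 shrinks the simulated FWHM", {
  offs <- seq(-5, 5, 0.1)
  z1 <- bmc_propagate(list(water_pool(1.8, 0.044)), std_pulse(), offs)
  z2 <- bmc_propagate(list(water_pool(1.8, 0.088)), std_pulse(), offs)
  expect_lt(spectrum_fwhm(z2), spectrum_fwhm(z1))
})
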