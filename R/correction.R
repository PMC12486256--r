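# Two-step T2 correction of DGE signals.
#
# The background (non-glucose) saturation level at the quantification offset
# is, in the spillover-dominant regime, approximately linear in T2:
#   S_background(dT2) = S0 + k dT2.                                 (linear)
# MTR_asym is attenuated by the square of the background level (scaled-down
# effect), MTR_asym ~ S_background^2 R_glucose / (cos^2 theta R1), so a T2
# excursion perturbs it by
#   dMTR(dT2) = scale [ (S0 + k dT2)^2 - S0^2 ],   scale = R_glc/(cos^2th R1)
# which is quadratic in dT2 and is fitted as a dT2^2 + b dT2 + c.
# Coefficients are derived from Bloch-McConnell simulations per tissue preset
# and applied with co-acquired dynamic T2 maps.

#' Correction model container
#'
#' Holds the linear background-sensitivity coefficient \code{k}, the quadratic
#' coefficients \code{(a, b, c)} of the background-induced MTR-asymmetry
#' excursion, the reference T2 and full calibration provenance.
#'
#' @param k Linear sensitivity of the background signal to T2 change
#'   (fractional signal per ms), or \code{NA}.
#' @param a,b,c Quadratic / linear / constant coefficients of
#'   background-induced delta MTR_asym versus delta T2 (per ms^2, per ms,
#'   dimensionless), or \code{NA}.
#' @param t2_ref Baseline T2 (ms).
#' @param s0 Background signal at the reference T2.
#' @param scale Scaled-down prefactor \code{R_glucose / (cos^2 theta R1)} used
#'   by the analytic background contribution.
#' @param calib Provenance list (pools, pulse, grid, residuals, ...).
#' @return Object of class \code{correction_model}.
#' @export
correction_model <- function(k = NA_real_, a = NA_real_, b = NA_real_,
                             c = NA_real_, t2_ref = NA_real_, s0 = NA_real_,
                             scale = NA_real_, calib = list()) {
  structure(list(k = k, a = a, b = b, c = c, t2_ref = t2_ref, s0 = s0,
                 scale = scale, calib = calib),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat("<correction model>\n")
  cat(sprintf("  t2_ref = %.1f ms, S0 = %.4f\n", x$t2_ref, x$s0))
  if (is.finite(x$k))
    cat(sprintf("  linear:    k = %.4e /ms  (R^2 = %.4f)\n", x$k,
                x$calib$linear_r2 %||% NA))
  if (is.finite(x$a))
    cat(sprintf("  quadratic: a = %.4e /ms^2, b = %.4e /ms, c = %.4e\n",
                x$a, x$b, x$c))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_t2_grid <- function(t2_ref) seq(t2_ref - 10, t2_ref + 10, length.out = 21)

# background-only simulated signal at the quantification offset per grid T2
simulate_background_signal <- function(pools, pulse, t2_grid) {
  vapply(t2_grid, function(t2ms) {
    pl <- set_water_t2(pools, t2ms)
    bmc_propagate(pl, pulse, pulse$offset)$signal
  }, numeric(1))
}

set_water_t2 <- function(pools, t2_ms) {
  pools <- pool_system(pools)
  pools[[1]]$r2 <- 1000 / t2_ms
  pools
}

#' Calibrate the linear single-offset background model
#'
#' Simulates the background (no-glucose) saturated signal at the
#' quantification offset across a T2 grid with the Bloch-McConnell propagator
#' and fits \code{S_background = S0 + k dT2} by least squares.
#'
#' @param background_pools Pool list without a glucose pool (water plus any
#'   magnetization-transfer background).
#' @param pulse A [saturation_pulse()]; its \code{offset} is the
#'   quantification offset (default +1.2 ppm).
#' @param t2_grid Water T2 values to simulate (ms); default
#'   \code{t2_ref +- 10} ms, 21 points, spanning the physiological excursion.
#' @param t2_ref Baseline T2 (ms).
#' @param glucose_ref Reference glucose concentration (mM) used only to store
#'   the analytic scaled-down prefactor for
#'   [background_mtr_contribution()]; default 10 mM.
#' @return A [correction_model()] with \code{k} fitted; linear fit R^2 is
#'   stored in \code{$calib$linear_r2} and a warning is raised if it falls
#'   below 0.99.
#' @export
calibrate_linear <- function(background_pools, pulse,
                             t2_grid = default_t2_grid(t2_ref),
                             t2_ref, glucose_ref = 10) {
  background_pools <- pool_system(background_pools)
  if (any(vapply(background_pools, function(p) p$delta == pulse$offset &&
                   !is_water(p), logical(1))))
    warning("background pool at the quantification offset: is glucose included?")
  if (length(t2_grid) < 3) stop("degenerate T2 grid: need >= 3 points")
  s_bg <- simulate_background_signal(background_pools, pulse, t2_grid)
  dT2 <- t2_grid - t2_ref
  fit <- stats::lm(s_bg ~ dT2)
  r2 <- summary(fit)$r.squared
  if (r2 < 0.99)
    warning(sprintf("background-vs-T2 linearity is poor (R^2 = %.4f); residual sd %.3e",
                    r2, stats::sd(stats::resid(fit))))
  w <- background_pools[[1]]
  pr <- pulse_at_offset(pulse, pulse$offset)
  th <- tilt_angle(pr)
  glc <- exchange_pool("glucose", 1.2, glucose_fraction(glucose_ref), 4000,
                       1.0, 0.015)
  scale <- r_st_pool(glc, pr) / (cos(th)^2 * w$r1)
  s0 <- unname(stats::predict(fit, data.frame(dT2 = 0)))
  correction_model(
    k = unname(stats::coef(fit)[2]), t2_ref = t2_ref, s0 = s0, scale = scale,
    calib = list(mode = "linear", linear_r2 = r2,
                 residual = max(abs(stats::resid(fit))),
                 t2_grid = t2_grid, glucose_ref = glucose_ref,
                 pulse = unclass(pulse)[c("b1", "t_sat", "offset", "b0")],
                 pools = lapply(background_pools, unclass)))
}

#' Analytic background-induced MTR-asymmetry excursion
#'
#' Evaluates the scaled-down relation with the calibrated linear background
#' model substituted in:
#' \code{dMTR(dT2) = scale [ (S0 + k dT2)^2 - S0^2 ]}. Exactly quadratic in
#' \code{dT2} and zero at \code{dT2 = 0}.
#'
#' @param model A [correction_model()] from [calibrate_linear()] (or
#'   [calibrate_quadratic()] run with the same provenance).
#' @param delta_t2 T2 change from baseline (ms), vectorized.
#' @return Background-induced delta MTR_asym (dimensionless).
#' @export
background_mtr_contribution <- function(model, delta_t2) {
  stopifnot(inherits(model, "correction_model"))
  if (!is.finite(model$k) || !is.finite(model$s0) || !is.finite(model$scale))
    stop("model is not calibrated (run calibrate_linear first)")
  model$scale * ((model$s0 + model$k * delta_t2)^2 - model$s0^2)
}

#' Calibrate the quadratic MTR-asymmetry background model
#'
#' Simulates MTR_asym at the quantification offset across a T2 grid with the
#' full pool system (glucose held at a fixed reference concentration) and
#' fits the background-induced excursion
#' \code{dMTR(dT2) = a dT2^2 + b dT2 + c}.
#'
#' @param full_pools Pool list including the glucose pool at the reference
#'   concentration (see [tissue_pools()]).
#' @inheritParams calibrate_linear
#' @param mode \code{"simulated"} (default) fits the Bloch-McConnell
#'   MTR_asym excursion directly; \code{"analytic"} fits the closed-form
#'   scaled-down curve from [background_mtr_contribution()].
#' @param model Optional [correction_model()] from [calibrate_linear()] whose
#'   \code{k}, \code{s0}, \code{scale} are retained (and required for
#'   \code{mode = "analytic"}).
#' @return A [correction_model()] with \code{a}, \code{b}, \code{c} fitted and
#'   the fit residual stored in \code{$calib$quad_residual}.
#' @export
calibrate_quadratic <- function(full_pools, pulse,
                                t2_grid = default_t2_grid(t2_ref), t2_ref,
                                mode = c("simulated", "analytic"),
                                model = NULL) {
  mode <- match.arg(mode)
  full_pools <- pool_system(full_pools)
  if (length(t2_grid) < 3) stop("degenerate T2 grid: need >= 3 points")
  dT2 <- t2_grid - t2_ref
  if (mode == "analytic") {
    if (is.null(model)) stop("analytic mode needs a linear-calibrated model")
    y <- background_mtr_contribution(model, dT2)
  } else {
    asym <- vapply(t2_grid, function(t2ms) {
      pl <- set_water_t2(full_pools, t2ms)
      zs <- bmc_propagate(pl, pulse, c(-abs(pulse$offset), abs(pulse$offset)))
      zs$signal[1] - zs$signal[2]
    }, numeric(1))
    ref <- asym[which.min(abs(dT2))]
    if (min(abs(dT2)) > 1e-9) {
      pl <- set_water_t2(full_pools, t2_ref)
      zs <- bmc_propagate(pl, pulse, c(-abs(pulse$offset), abs(pulse$offset)))
      ref <- zs$signal[1] - zs$signal[2]
    }
    y <- asym - ref
  }
  fit <- stats::lm(y ~ dT2 + I(dT2^2))
  co <- stats::coef(fit)
  resid <- max(abs(stats::resid(fit)))
  if (resid > 1e-3)
    warning(sprintf("quadratic background fit residual %.2e exceeds 1e-3", resid))
  out <- if (is.null(model)) correction_model(t2_ref = t2_ref) else model
  out$a <- unname(co[3]); out$b <- unname(co[2]); out$c <- unname(co[1])
  out$t2_ref <- t2_ref
  out$calib$quad_mode <- mode
  out$calib$quad_residual <- resid
  out$calib$t2_grid <- t2_grid
  out
}

#' Dynamic T2 record
#'
#' @param time Acquisition times (s).
#' @param t2 T2 per timepoint (ms; ROI scalar series).
#' @param baseline_idx Pre-injection timepoints defining the T2 baseline.
#' @return Object of class \code{dynamic_t2} with \code{delta_t2 = t2 - }
#'   mean baseline T2.
#' @export
dynamic_t2 <- function(time, t2, baseline_idx) {
  stopifnot(length(time) == length(t2))
  if (length(baseline_idx) == 0 || max(baseline_idx) > length(t2))
    stop("invalid baseline_idx")
  ref <- mean(t2[baseline_idx], na.rm = TRUE)
  structure(list(time = as.numeric(time), t2 = as.numeric(t2),
                 baseline_idx = as.integer(baseline_idx),
                 t2_ref = ref, delta_t2 = as.numeric(t2) - ref),
            class = "dynamic_t2")
}

check_alignment <- function(series, t2) {
  if (length(series$time) != length(t2$time))
    stop("DGE series and dynamic T2 have different lengths")
  frame <- stats::median(diff(series$time))
  if (any(abs(series$time - t2$time) > frame / 2, na.rm = TRUE))
    stop("time axes misaligned by more than half a frame interval")
}

#' Correct a single-offset DGE time course for T2 drift
#'
#' Removes the T2-driven fractional background change from the single-offset
#' DGE curve: the background signal shifts by \code{k dT2(t)}, which enters
#' the percent DGE as \code{-100 k dT2(t) / S_baseline}; that term is
#' subtracted. Timepoints with missing dT2 are flagged \code{NA}.
#'
#' @param series A [dge_series()] processed by [single_offset_dge()].
#' @param t2 A [dynamic_t2()] aligned with the series.
#' @param model A [correction_model()] with \code{k}.
#' @return The series with \code{$dge_corrected} filled in.
#' @export
correct_single_offset <- function(series, t2, model) {
  stopifnot(inherits(series, "dge_series"), inherits(t2, "dynamic_t2"),
            inherits(model, "correction_model"))
  if (!is.finite(model$k)) stop("model carries no linear coefficient k")
  if (is.null(series$dge)) series <- single_offset_dge(series)
  check_alignment(series, t2)
  bg <- 100 * (-model$k * t2$delta_t2) / series$s_baseline
  series$dge_corrected <- series$dge - bg
  series
}

#' Correct an MTR-asymmetry DGE time course for T2 drift
#'
#' Subtracts the fitted background-induced excursion, anchored to zero at
#' \code{dT2 = 0} so baseline neutrality is preserved:
#' \code{dge_asym_corr(t) = dge_asym(t) - 100 [a dT2^2 + b dT2]}.
#'
#' @inheritParams correct_single_offset
#' @param model A [correction_model()] with \code{a}, \code{b}, \code{c}.
#' @return The series with \code{$dge_asym_corrected} filled in.
#' @export
correct_mtr_asym <- function(series, t2, model) {
  stopifnot(inherits(series, "dge_series"), inherits(t2, "dynamic_t2"),
            inherits(model, "correction_model"))
  if (!is.finite(model$a) || !is.finite(model$b))
    stop("model carries no quadratic coefficients (run calibrate_quadratic)")
  if (is.null(series$dge_asym)) series <- mtr_asym_dge(series)
  check_alignment(series, t2)
  bg <- 100 * (model$a * t2$delta_t2^2 + model$b * t2$delta_t2)
  series$dge_asym_corrected <- series$dge_asym - bg
  series
}

#' Pearson decoupling report
#'
#' Correlates the DGE time courses (original and corrected, both
#' quantification modes where present) with the dynamic T2 values and reports
#' Pearson R with two-sided P-values. A successful correction drives
#' \code{|R|} towards zero.
#'
#' @param series A [dge_series()] with DGE (and optionally corrected) fields.
#' @param t2 A [dynamic_t2()].
#' @return Data frame with columns \code{metric}, \code{phase}, \code{r},
#'   \code{p}, \code{n}. Constant series yield \code{NA} with a flag rather
#'   than an error.
#' @export
decoupling_report <- function(series, t2) {
  stopifnot(inherits(series, "dge_series"), inherits(t2, "dynamic_t2"))
  pairs <- list(
    c("single_offset", "original", "dge"),
    c("single_offset", "corrected", "dge_corrected"),
    c("mtr_asym", "original", "dge_asym"),
    c("mtr_asym", "corrected", "dge_asym_corrected"))
  rows <- lapply(pairs, function(p) {
    y <- series[[p[3]]]
    if (is.null(y)) return(NULL)
    keep <- is.finite(y) & is.finite(t2$t2)
    if (sum(keep) < 3) stop("need >= 3 paired samples")
    if (stats::sd(y[keep]) == 0 || stats::sd(t2$t2[keep]) == 0) {
      return(data.frame(metric = p[1], phase = p[2], r = NA_real_,
                        p = NA_real_, n = sum(keep),
                        flag = "constant-series"))
    }
    ct <- stats::cor.test(y[keep], t2$t2[keep])
    data.frame(metric = p[1], phase = p[2], r = unname(ct$estimate),
               p = ct$p.value, n = sum(keep), flag = "")
  })
  do.call(rbind, rows)
}
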