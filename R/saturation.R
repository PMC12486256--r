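# Analytical rotating-frame (R1rho) saturation model.
#
# The normalized water signal under a long rectangular pulse relaxes
# mono-exponentially towards its steady state at rate R1rho, the rotating-frame
# relaxation rate along the effective field. R1rho decomposes into the
# effective water term R_eff = cos^2(theta) R1 + sin^2(theta) R2 and an
# additive exchange-mediated term R_ST summed over solute pools.

#' Tilt angle of the effective saturation field
#'
#' Angle between the effective field and the z axis, \code{atan(omega1/Delta)}
#' with both in angular frequency. Only even powers of the angle enter the
#' saturation model, so the magnitude of the offset is used and the angle lies
#' in (0, pi/2].
#'
#' @param pulse A [saturation_pulse()].
#' @return Tilt angle (rad).
#' @examples
#' tilt_angle(saturation_pulse(2, 2, offset = 1.2))
#' @export
tilt_angle <- function(pulse) {
  stopifnot(inherits(pulse, "saturation_pulse"))
  if (pulse$omega1 == 0 && pulse$d_omega == 0)
    stop("tilt angle undefined: b1 = 0 and offset = 0")
  atan2(pulse$omega1, abs(pulse$d_omega))
}

#' Effective rotating-frame relaxation rate of water
#'
#' \code{cos^2(theta) r1 + sin^2(theta) r2}: the water relaxation rate along
#' the effective field in the absence of exchange.
#'
#' @param r1,r2 Longitudinal and transverse rates (s^-1, > 0).
#' @param theta Tilt angle (rad).
#' @return Rate (s^-1), bounded by \code{min(r1, r2)} and \code{max(r1, r2)}.
#' @export
r_eff <- function(r1, r2, theta) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("relaxation rates must be > 0")
  cos(theta)^2 * r1 + sin(theta)^2 * r2
}

# Exchange-mediated rotating-frame relaxation contribution of one dilute pool.
# Dilute-limit dispersion formula with an R2 correction in the denominator;
# reduces to f * k * omega1^2 / (omega1^2 + k (k + R2s)) on the solute
# resonance when the shift dominates omega1 (the usual labeling efficiency).
r_st_pool <- function(pool, pulse) {
  if (pool$fraction == 0 || pool$k_ex == 0) return(0)
  w1 <- pulse$omega1
  dw <- pulse$d_omega                       # rf offset from water (rad/s)
  db <- ppm_to_radsec(pool$delta, pulse$b0, pulse$gamma)  # pool shift (rad/s)
  sin2 <- w1^2 / (w1^2 + dw^2)
  denom <- (db - dw)^2 + w1^2 + pool$k_ex * (pool$k_ex + pool$r2)
  sin2 * pool$fraction * pool$k_ex * db^2 / denom
}

#' Apparent saturation-transfer rate of a pool system
#'
#' Sums the exchange-mediated rotating-frame relaxation contributions of all
#' non-water pools (additivity of dilute pools).
#'
#' @param pools Pool list (see [pool_system()]).
#' @param pulse A [saturation_pulse()].
#' @return Rate (s^-1).
#' @export
r_st <- function(pools, pulse) {
  pools <- pool_system(pools)
  sum(vapply(pools[-1], r_st_pool, numeric(1), pulse = pulse))
}

saturation_response <- function(theta, reff, rst, r1w, spillover_approx, t_sat = NULL,
                                z_initial = 1) {
  r1rho <- reff + rst
  s_ss <- cos(theta)^2 * r1w / r1rho
  s_t <- if (is.null(t_sat)) NA_real_ else {
    (cos(theta)^2 * z_initial - s_ss) * exp(-r1rho * t_sat) + s_ss
  }
  structure(
    list(theta = theta, r_eff = reff, r_st = rst, r1rho = r1rho,
         s_ss = s_ss, s_t = s_t, spillover_approx = spillover_approx),
    class = "saturation_response")
}

#' @export
print.saturation_response <- function(x, ...) {
  cat(sprintf(
    "<saturation response> theta=%.3f rad  R_eff=%.3g  R_ST=%.3g  R1rho=%.3g /s\n  S_ss=%.4f  S(t_sat)=%s%s\n",
    x$theta, x$r_eff, x$r_st, x$r1rho, x$s_ss,
    ifelse(is.na(x$s_t), "NA", sprintf("%.4f", x$s_t)),
    if (isTRUE(x$spillover_approx)) "  [spillover-dominant approximation]" else ""))
  invisible(x)
}

#' Steady-state saturated signal from rotating-frame theory
#'
#' Computes the tilt angle, effective relaxation, pool-additive saturation
#' transfer rate and the steady-state normalized signal
#' \code{S_ss = cos^2(theta) R1 / R1rho}.
#'
#' @param pools Pool list; exactly one water pool required.
#' @param pulse A [saturation_pulse()].
#' @param spillover_approx If \code{TRUE}, return the spillover-dominant
#'   approximation \code{S_ss ~ cos^2(theta) R1 / (sin^2(theta) R2)}, valid
#'   when \code{R2} dominates the rotating-frame rate. This form is linear in
#'   T2 and underlies the linear single-offset correction model.
#' @return A \code{saturation_response} with fields \code{theta},
#'   \code{r_eff}, \code{r_st}, \code{r1rho}, \code{s_ss}, \code{s_t}.
#' @examples
#' pools <- list(water_pool(1.8, 0.0443))
#' steady_state_signal(pools, saturation_pulse(2, 2, 1.2))
#' @export
steady_state_signal <- function(pools, pulse, spillover_approx = FALSE) {
  pools <- pool_system(pools)
  w <- pools[[1]]
  th <- tilt_angle(pulse)
  reff <- r_eff(w$r1, w$r2, th)
  rst <- sum(vapply(pools[-1], r_st_pool, numeric(1), pulse = pulse))
  if (spillover_approx) {
    resp <- saturation_response(th, reff, rst, w$r1, FALSE)
    resp$s_ss <- cos(th)^2 * w$r1 / (sin(th)^2 * w$r2)
    resp$spillover_approx <- TRUE
    return(resp)
  }
  saturation_response(th, reff, rst, w$r1, FALSE)
}

#' Transient saturated signal from rotating-frame theory
#'
#' Mono-exponential approach of the normalized signal from the projected
#' initial condition \code{cos^2(theta) * z_initial} to the steady state at
#' rate R1rho:
#' \code{S(t) = (cos^2(theta) z_i - S_ss) exp(-R1rho t_sat) + S_ss}.
#'
#' @inheritParams steady_state_signal
#' @param z_initial Longitudinal magnetization before the pulse, relative to
#'   equilibrium (default 1, fully relaxed: long TR).
#' @return A \code{saturation_response} with \code{s_t} filled in.
#' @export
transient_signal <- function(pools, pulse, z_initial = 1) {
  pools <- pool_system(pools)
  if (pulse$t_sat <= 0) stop("t_sat must be > 0")
  w <- pools[[1]]
  th <- tilt_angle(pulse)
  reff <- r_eff(w$r1, w$r2, th)
  rst <- sum(vapply(pools[-1], r_st_pool, numeric(1), pulse = pulse))
  saturation_response(th, reff, rst, w$r1, FALSE, t_sat = pulse$t_sat,
                      z_initial = z_initial)
}
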