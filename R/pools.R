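#' Gyromagnetic ratio of the proton
#'
#' @format Scalar, rad s^-1 T^-1.
#' @export
GAMMA_H <- 267.522187e6

#' Water proton concentration used for fraction bookkeeping (mM)
#' @noRd
WATER_PROTON_MM <- 2 * 55500

ppm_to_radsec <- function(ppm, b0, gamma = GAMMA_H) {
  ppm * 1e-6 * gamma * b0
}

#' Define an exchanging proton pool
#'
#' A pool is characterised by its chemical shift relative to water, its proton
#' fraction relative to water protons, the solute-to-water exchange rate and
#' its intrinsic relaxation rates. The water pool itself has \code{delta = 0},
#' \code{fraction = 1} and \code{k_ex = 0}.
#'
#' @param name Label for the pool (e.g. \code{"water"}, \code{"glucose"}).
#' @param delta Chemical shift relative to water (ppm).
#' @param fraction Proton fraction relative to water protons (>= 0).
#' @param k_ex Solute-to-water exchange rate (s^-1, >= 0).
#' @param t1 Longitudinal relaxation time (s, > 0).
#' @param t2 Transverse relaxation time (s, > 0).
#' @return An object of class \code{exchange_pool} with fields \code{name},
#'   \code{delta}, \code{fraction}, \code{k_ex}, \code{r1} and \code{r2}
#'   (rates, s^-1).
#' @examples
#' water_pool(t1 = 1.8, t2 = 0.0443)
#' exchange_pool("glucose", delta = 1.2, fraction = 5e-4, k_ex = 4000,
#'               t1 = 1.0, t2 = 0.015)
#' @export
exchange_pool <- function(name, delta, fraction, k_ex, t1, t2) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(fraction) || fraction < 0)
    stop("pool '", name, "': fraction must be >= 0")
  if (!is.finite(k_ex) || k_ex < 0)
    stop("pool '", name, "': k_ex must be >= 0")
  if (!is.finite(t1) || t1 <= 0 || !is.finite(t2) || t2 <= 0)
    stop("pool '", name, "': t1 and t2 must be > 0")
  structure(
    list(name = name, delta = as.numeric(delta), fraction = as.numeric(fraction),
         k_ex = as.numeric(k_ex), r1 = 1 / t1, r2 = 1 / t2),
    class = "exchange_pool")
}

#' @rdname exchange_pool
#' @export
water_pool <- function(t1, t2) {
  exchange_pool("water", delta = 0, fraction = 1, k_ex = 0, t1 = t1, t2 = t2)
}

is_water <- function(pool) pool$fraction == 1 && pool$delta == 0 && pool$k_ex == 0

#' @export
print.exchange_pool <- function(x, ...) {
  cat(sprintf("<pool %s> delta=%.2f ppm  f=%.3g  k=%.3g /s  R1=%.3g /s  R2=%.3g /s\n",
              x$name, x$delta, x$fraction, x$k_ex, x$r1, x$r2))
  invisible(x)
}

#' Validate and order a pool system
#'
#' Checks that exactly one water pool is present and returns the list with the
#' water pool first.
#' @param pools List of \code{exchange_pool} objects.
#' @return The reordered list.
#' @export
pool_system <- function(pools) {
  if (inherits(pools, "exchange_pool")) pools <- list(pools)
  if (length(pools) == 0) stop("empty pool list")
  ok <- vapply(pools, inherits, logical(1), "exchange_pool")
  if (!all(ok)) stop("all elements must be exchange_pool objects")
  iw <- which(vapply(pools, is_water, logical(1)))
  if (length(iw) != 1L)
    stop("pool system must contain exactly one water pool (delta = 0, fraction = 1)")
  c(pools[iw], pools[-iw])
}

#' Define a rectangular saturation pulse
#'
#' @param b1 Irradiation amplitude (microtesla, >= 0).
#' @param t_sat Saturation duration (s, > 0).
#' @param offset Saturation frequency offset from water (ppm). Positive values
#'   are downfield of water; the glucose hydroxyl resonance sits at +1.2 ppm.
#' @param b0 Static field strength (T, default 7).
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1).
#' @return Object of class \code{saturation_pulse} with derived angular
#'   quantities \code{omega1} (rad/s) and \code{d_omega} (rad/s).
#' @examples
#' saturation_pulse(b1 = 2, t_sat = 2, offset = 1.2)
#' @export
saturation_pulse <- function(b1, t_sat, offset = 1.2, b0 = 7, gamma = GAMMA_H) {
  if (!is.finite(b1) || b1 < 0) stop("b1 must be >= 0")
  if (!is.finite(t_sat) || t_sat <= 0) stop("t_sat must be > 0")
  if (!is.finite(b0) || b0 <= 0) stop("b0 must be > 0")
  structure(
    list(b1 = as.numeric(b1), t_sat = as.numeric(t_sat),
         offset = as.numeric(offset), b0 = as.numeric(b0), gamma = gamma,
         omega1 = gamma * b1 * 1e-6,
         d_omega = ppm_to_radsec(offset, b0, gamma)),
    class = "saturation_pulse")
}

#' @export
print.saturation_pulse <- function(x, ...) {
  cat(sprintf("<saturation pulse> B1=%.2f uT  t_sat=%.2f s  offset=%+.2f ppm  B0=%.1f T\n",
              x$b1, x$t_sat, x$offset, x$b0))
  invisible(x)
}

#' @rdname saturation_pulse
#' @param pulse A \code{saturation_pulse} to re-tune.
#' @export
pulse_at_offset <- function(pulse, offset) {
  pulse$offset <- offset
  pulse$d_omega <- ppm_to_radsec(offset, pulse$b0, pulse$gamma)
  pulse
}

#' Proton fraction of a glucose solution
#'
#' Converts a glucose concentration to the exchangeable-proton fraction of the
#' lumped hydroxyl pool, assuming \code{n_oh} exchangeable hydroxyl protons per
#' molecule against the 2 x 55.5 M water proton background.
#'
#' @param conc_mM Glucose concentration (mM, >= 0).
#' @param n_oh Exchangeable hydroxyl protons per molecule (default 5).
#' @return Dimensionless proton fraction.
#' @examples
#' glucose_fraction(20)
#' @export
glucose_fraction <- function(conc_mM, n_oh = 5) {
  if (any(conc_mM < 0)) stop("concentration must be >= 0")
  conc_mM * n_oh / WATER_PROTON_MM
}

#' Glucose-dependent transverse relaxation rate
#'
#' Chemical exchange with glucose hydroxyls raises the tissue transverse
#' relaxation rate linearly with the concentration change:
#' \code{R2_glc = R2_water + r2ex * conc}.
#'
#' @param conc Glucose concentration change (mM, >= 0).
#' @param r2_water Tissue transverse rate without glucose change (s^-1).
#' @param r2ex Transverse relaxivity of glucose (s^-1 mM^-1); the default
#'   0.053 applies at 7 T.
#' @return Transverse relaxation rate (s^-1).
#' @examples
#' glucose_r2(10, r2_water = 14)   # 14.53
#' @export
glucose_r2 <- function(conc, r2_water, r2ex = 0.053) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentration change must be >= 0 (signed T2 excursions are handled downstream)")
  if (r2ex < 0) stop("r2ex must be >= 0")
  r2_water + r2ex * conc
}

#' @rdname glucose_r2
#' @param t2_water_ms Baseline transverse relaxation time (ms).
#' @return \code{glucose_t2_ms}: transverse relaxation time (ms) after the
#'   concentration change.
#' @export
glucose_t2_ms <- function(conc, t2_water_ms, r2ex = 0.053) {
  1000 / glucose_r2(conc, 1000 / t2_water_ms, r2ex)
}
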