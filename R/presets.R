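# Tissue presets for calibration and simulation. Pool parameters follow
# literature-informed values for 7 T and are fully overridable through
# exchange_pool() or the YAML/JSON config schema (read_pool_config).

#' Tissue pool presets
#'
#' Returns a pool system for one of three calibration regimes:
#' \describe{
#'   \item{phantom}{Gd-DTPA-doped glucose solution: water only
#'     (T1 = 300 ms, T2 = 100 ms), no semi-solid background.}
#'   \item{brain}{Rat brain parenchyma at 7 T: water T1 = 1.8 s,
#'     T2 = 44.3 ms, plus a lumped Lorentzian magnetization-transfer
#'     background pool (-2.4 ppm, fraction 0.05, k = 50 /s).}
#'   \item{tumor}{Subcutaneous tumor: water T1 = 2.0 s, T2 = 47.5 ms, smaller
#'     MT fraction (0.03).}
#' }
#' A lumped glucose hydroxyl pool (+1.2 ppm, 5 exchangeable protons per
#' molecule, k = 4000 /s) is appended when \code{glucose_mM > 0}.
#'
#' @param preset One of \code{"brain"}, \code{"tumor"}, \code{"phantom"}.
#' @param glucose_mM Glucose concentration (mM, >= 0).
#' @param t2_water_ms Override for the water T2 (ms); \code{NULL} keeps the
#'   preset baseline.
#' @param k_glc,n_oh Glucose exchange rate (s^-1) and exchangeable protons per
#'   molecule.
#' @return Pool list (water first).
#' @examples
#' tissue_pools("brain", glucose_mM = 10)
#' @export
tissue_pools <- function(preset = c("brain", "tumor", "phantom"),
                         glucose_mM = 0, t2_water_ms = NULL,
                         k_glc = 4000, n_oh = 5) {
  preset <- match.arg(preset)
  base <- switch(preset,
    phantom = list(t1 = 0.3, t2 = 0.1, mtc = NULL),
    brain = list(t1 = 1.8, t2 = 0.0443,
                 mtc = exchange_pool("mtc", -2.4, 0.05, 50, 1.0, 1e-5)),
    tumor = list(t1 = 2.0, t2 = 0.0475,
                 mtc = exchange_pool("mtc", -2.4, 0.03, 50, 1.0, 1e-5)))
  t2 <- if (is.null(t2_water_ms)) base$t2 else t2_water_ms / 1000
  pools <- list(water_pool(base$t1, t2))
  if (!is.null(base$mtc)) pools <- c(pools, list(base$mtc))
  if (glucose_mM > 0)
    pools <- c(pools, list(exchange_pool(
      "glucose", 1.2, glucose_fraction(glucose_mM, n_oh), k_glc, 1.0, 0.015)))
  pools
}

#' Baseline water T2 of a preset (ms)
#' @param preset Preset name.
#' @export
preset_t2_ref <- function(preset = c("brain", "tumor", "phantom")) {
  preset <- match.arg(preset)
  switch(preset, brain = 44.3, tumor = 47.5, phantom = 100)
}

#' Canonical in vivo DGE offset schedule (ppm)
#'
#' @return \code{c(-2, -1.5, -1.2, -0.9, 0, 0.9, 1.2, 1.5, 2)}.
#' @export
dge_offsets <- function() c(-2, -1.5, -1.2, -0.9, 0, 0.9, 1.2, 1.5, 2)
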