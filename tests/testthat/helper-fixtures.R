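# Shared fixtures. Everything is generated in code; calibrations are cached
# per session because several files exercise the same models.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

std_pulse <- function(offset = 1.2, b1 = 2, t_sat = 2)
  saturation_pulse(b1, t_sat, offset)

two_pool <- function(conc = 20, t2_ms = 44.3)
  list(water_pool(1.8, t2_ms / 1000),
       exchange_pool("glucose", 1.2, glucose_fraction(conc), 4000, 1, 0.015))

brain_model <- function() fixture("brain_model", function() {
  t2r <- preset_t2_ref("brain")
  m <- suppressWarnings(
    calibrate_linear(tissue_pools("brain"), std_pulse(), t2_ref = t2r))
  calibrate_quadratic(tissue_pools("brain", 10), std_pulse(), t2_ref = t2r,
                      model = m)
})

# tumor-regime fixtures for the null / combined experiments: plateau derived
# from the reported tumor excursion 47.5 -> 44.0 ms
tumor_plateau <- function() plateau_for_t2(47.5, 44.0)

tumor_grid <- function() seq(47.5 - 5, 47.5 + 5, length.out = 21)

tumor_model_combined <- function() fixture("tumor_model_combined", function() {
  t2r <- preset_t2_ref("tumor")
  m <- suppressWarnings(calibrate_linear(tissue_pools("tumor"), std_pulse(),
                                         tumor_grid(), t2r,
                                         glucose_ref = tumor_plateau()))
  calibrate_quadratic(tissue_pools("tumor", tumor_plateau()), std_pulse(),
                      tumor_grid(), t2r, model = m)
})

tumor_model_static <- function() fixture("tumor_model_static", function() {
  t2r <- preset_t2_ref("tumor")
  m <- suppressWarnings(
    calibrate_linear(tissue_pools("tumor", tumor_plateau()), std_pulse(),
                     tumor_grid(), t2r, glucose_ref = tumor_plateau()))
  calibrate_quadratic(tissue_pools("tumor", tumor_plateau()), std_pulse(),
                      tumor_grid(), t2r, model = m)
})

# short noiseless tumor-regime protocol shared by correction tests
short_proto <- function(noise = "none", grid = c(4, 4), snr = 50)
  dynamic_protocol(n_frames = 40, n_baseline = 10, plateau = tumor_plateau(),
                   noise = noise, snr = snr, grid = grid)

# DGE series straight from simulator ground truth (noiseless path)
truth_series <- function(sim, proto, offset = 1.2) {
  io_p <- which(proto$offsets == offset)
  io_n <- which(proto$offsets == -offset)
  s <- dge_series(proto$time, sim$truth$s[io_p, ], seq_len(proto$n_baseline),
                  offset = offset,
                  mtr_asym = sim$truth$s[io_n, ] - sim$truth$s[io_p, ])
  mtr_asym_dge(single_offset_dge(s))
}

truth_t2 <- function(sim, proto)
  dynamic_t2(proto$time, sim$truth$t2_ms, seq_len(proto$n_baseline))
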