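# Synthetic data: digital glucose phantoms and dynamic DGE experiments with
# coupled glucose/T2 time courses, multi-echo readout and seeded noise. These
# stand in for scanner data throughout the test suite.

#' Glucose uptake concentration curve
#'
#' Deterministic smooth curve: zero before infusion, then either a monotone
#' sigmoid rise to the plateau or a gamma-variate rise-then-settle.
#'
#' @param time Frame times (s).
#' @param plateau Plateau concentration change (mM, >= 0).
#' @param t_start Infusion start (s).
#' @param t_peak Time to reach ~90\% of plateau (sigmoid) or the peak
#'   (gamma), measured from \code{t_start} (s).
#' @param shape \code{"sigmoid"} or \code{"gamma"}.
#' @return Concentration per frame (mM).
#' @examples
#' make_uptake_curve(seq(0, 2700, 45), plateau = 66, t_start = 450)
#' @export
make_uptake_curve <- function(time, plateau, t_start, t_peak = 600,
                              shape = c("sigmoid", "gamma")) {
  shape <- match.arg(shape)
  if (plateau < 0) stop("plateau must be >= 0")
  tt <- pmax(time - t_start, 0)
  conc <- if (shape == "sigmoid") {
    tau <- t_peak / log(9)          # reaches 90% of plateau at t_peak
    plateau * (1 - exp(-tt / tau))
  } else {
    alpha <- 3; beta <- t_peak / alpha
    g <- (tt / (alpha * beta))^alpha * exp(alpha - tt / beta)
    plateau * g
  }
  conc[time < t_start] <- 0
  conc
}

#' Plateau concentration reproducing a printed T2 excursion
#'
#' Inverts the glucose relaxivity relation: the concentration change that
#' takes the baseline T2 to the plateau T2,
#' \code{(1000/t2_plateau - 1000/t2_base) / r2ex}.
#'
#' @param t2_base,t2_plateau Baseline and plateau T2 (ms).
#' @param r2ex Glucose transverse relaxivity (s^-1 mM^-1).
#' @return Concentration change (mM). The reported brain excursion
#'   (44.3 -> 43.0 ms) maps to ~12.9 mM; the tumor excursion
#'   (47.5 -> 44.0 ms) to ~31.6 mM.
#' @export
plateau_for_t2 <- function(t2_base, t2_plateau, r2ex = 0.053) {
  if (t2_plateau > t2_base) stop("plateau T2 must not exceed baseline T2")
  (1000 / t2_plateau - 1000 / t2_base) / r2ex
}

#' Dynamic DGE acquisition protocol
#'
#' Defaults mirror the in vivo schedule: 10 baseline frames, 45 s per image
#' pair, offsets +-2.0/+-1.5/+-1.2/+-0.9/0 ppm, 5 echoes at 25 ms spacing,
#' 2 uT / 2 s saturation, Rician noise at SNR 50 on the first echo.
#'
#' @param n_frames Total dynamic frames.
#' @param n_baseline Pre-injection frames.
#' @param frame_interval Seconds per frame.
#' @param offsets Offset schedule (ppm).
#' @param echo_train An [echo_train()].
#' @param pulse A [saturation_pulse()].
#' @param plateau Glucose plateau (mM).
#' @param t_peak Uptake time constant parameter (s), see
#'   [make_uptake_curve()].
#' @param shape Uptake curve shape.
#' @param r2ex Glucose transverse relaxivity (s^-1 mM^-1).
#' @param noise \code{"rician"}, \code{"gaussian"} or \code{"none"}.
#' @param snr First-echo baseline SNR.
#' @param grid Spatial grid (rows, cols) of the homogeneous ROI.
#' @return Object of class \code{dynamic_protocol}; \code{conc_curve} and
#'   \code{t2_curve} are filled in by [simulate_dge_experiment()] from the
#'   tissue baseline T2.
#' @export
dynamic_protocol <- function(n_frames = 60, n_baseline = 10,
                             frame_interval = 45, offsets = dge_offsets(),
                             echo_train = NULL,
                             pulse = saturation_pulse(2, 2),
                             plateau = plateau_for_t2(44.3, 43.0),
                             t_peak = 600, shape = "sigmoid",
                             r2ex = 0.053, noise = "rician", snr = 50,
                             grid = c(4, 4)) {
  stopifnot(n_baseline >= 1, n_frames > n_baseline)
  if (is.null(echo_train)) echo_train <- default_echo_train()
  structure(list(n_frames = n_frames, n_baseline = n_baseline,
                 frame_interval = frame_interval, offsets = offsets,
                 echo_train = echo_train, pulse = pulse, plateau = plateau,
                 t_peak = t_peak, shape = shape, r2ex = r2ex, noise = noise,
                 snr = snr, grid = grid,
                 time = (seq_len(n_frames) - 1) * frame_interval,
                 infusion_start = n_baseline * frame_interval),
            class = "dynamic_protocol")
}

add_noise <- function(x, sigma, model) {
  if (model == "none" || sigma == 0) return(x)
  n <- length(x)
  if (model == "gaussian") return(x + stats::rnorm(n, 0, sigma))
  sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Simulate a dynamic glucose-enhanced experiment
#'
#' For every frame, derives the glucose concentration from the uptake curve
#' and the coupled T2 from the glucose relaxivity relation
#' (\code{R2(t) = R2_water + r2ex conc(t)}, enforced exactly), simulates the
#' Z-spectrum signals at the scheduled offsets with the Bloch-McConnell
#' propagator, synthesizes multi-echo images with \code{exp(-TE/T2(t))} decay
#' and seeded noise, and returns the stack plus the full ground truth.
#'
#' @param protocol A [dynamic_protocol()].
#' @param preset Tissue preset for the pool system, see [tissue_pools()].
#' @param seed Integer seed for the noise stream (mandatory when noise is on).
#' @param pd Proton density amplitude (arbitrary units).
#' @param t2_coupling If \code{FALSE}, hold T2 at baseline (glucose-only
#'   reference experiment). If \code{"only"}, hold glucose constant at
#'   \code{glucose_const} but apply the T2 ramp (null experiment isolating
#'   the T2 artifact).
#' @param glucose_const Constant glucose level (mM) for
#'   \code{t2_coupling = "only"}. Default 0; set it to the plateau to probe
#'   the MTR-asymmetry scaled-down artifact, which requires glucose present.
#' @return List with \code{stack} (a 5D [multi_echo_stack()]:
#'   row, col, echo, offset, time), \code{unsat} (3D unsaturated reference
#'   stack), and \code{truth} (conc, t2_ms, and the noiseless signal matrix
#'   offsets x frames).
#' @export
simulate_dge_experiment <- function(protocol, preset = "brain", seed = 1,
                                    pd = 1000, t2_coupling = TRUE,
                                    glucose_const = 0) {
  stopifnot(inherits(protocol, "dynamic_protocol"))
  p <- protocol
  t2_ref <- preset_t2_ref(preset)
  conc <- make_uptake_curve(p$time, p$plateau, p$infusion_start, p$t_peak,
                            p$shape)
  t2_only <- identical(t2_coupling, "only")
  t2_ms <- if (isTRUE(t2_coupling) || t2_only)
    glucose_t2_ms(conc, t2_ref, p$r2ex) else rep(t2_ref, p$n_frames)
  conc_eff <- if (t2_only) rep(glucose_const, p$n_frames) else conc
  # signal table: one BMC solve per unique (conc, t2) state
  key <- paste(signif(conc_eff, 10), signif(t2_ms, 10))
  sigtab <- matrix(NA_real_, length(p$offsets), p$n_frames)
  cache <- list()
  for (f in seq_len(p$n_frames)) {
    k <- key[f]
    if (is.null(cache[[k]])) {
      pools <- tissue_pools(preset, glucose_mM = conc_eff[f],
                            t2_water_ms = t2_ms[f])
      cache[[k]] <- bmc_propagate(pools, p$pulse, p$offsets)$signal
    }
    sigtab[, f] <- cache[[k]]
  }
  te <- p$echo_train$te_eff
  nvox <- prod(p$grid)
  sigma <- if (p$noise == "none") 0 else {
    pd * exp(-te[1] / t2_ref) / p$snr
  }
  set.seed(as.integer(seed))
  dims <- c(p$grid, p$echo_train$n_echoes, length(p$offsets), p$n_frames)
  data <- array(0, dims)
  for (f in seq_len(p$n_frames)) for (o in seq_along(p$offsets)) {
    clean <- pd * sigtab[o, f] * exp(-te / t2_ms[f])
    plane <- rep(clean, each = nvox)
    data[, , , o, f] <- add_noise(plane, sigma, p$noise)
  }
  unsat_clean <- pd * exp(-te / t2_ms[1])
  unsat <- array(add_noise(rep(unsat_clean, each = nvox), sigma, p$noise),
                 c(p$grid, p$echo_train$n_echoes))
  list(
    stack = multi_echo_stack(data, p$echo_train, offsets = p$offsets,
                             time = p$time),
    unsat = multi_echo_stack(unsat, p$echo_train),
    truth = list(conc = conc_eff, t2_ms = t2_ms, s = sigtab,
                 offsets = p$offsets, time = p$time, t2_ref = t2_ref,
                 baseline_idx = seq_len(p$n_baseline)))
}

#' Digital glucose phantom specification
#'
#' @param conc Tube glucose concentrations (mM); default the six-tube set
#'   \{10, 50, 100, 150, 230, 310\}.
#' @param grid Image dimensions (rows, cols).
#' @param tube_radius Tube radius (pixels).
#' @param t2_base Baseline (Gd-DTPA-shortened) water T2 common to all tubes
#'   before the glucose contribution (ms).
#' @param pd Tube proton density.
#' @param centers Optional 2-column matrix of tube centres; default ring
#'   layout.
#' @return Object of class \code{phantom_spec}. Tubes must not overlap.
#' @export
phantom_spec <- function(conc = c(10, 50, 100, 150, 230, 310),
                         grid = c(48, 48), tube_radius = 5,
                         t2_base = 100, pd = 1000, centers = NULL) {
  n <- length(conc)
  if (is.null(centers)) {
    ang <- 2 * pi * (seq_len(n) - 1) / n
    r <- min(grid) / 2 - tube_radius - 2
    centers <- cbind(grid[1] / 2 + r * cos(ang), grid[2] / 2 + r * sin(ang))
  }
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  if (any(d < 2 * tube_radius)) stop("tubes overlap")
  structure(list(conc = conc, grid = grid, tube_radius = tube_radius,
                 t2_base = t2_base, pd = pd, centers = centers),
            class = "phantom_spec")
}

tube_masks <- function(spec) {
  g <- spec$grid
  rows <- matrix(seq_len(g[1]), g[1], g[2])
  cols <- matrix(seq_len(g[2]), g[1], g[2], byrow = TRUE)
  lapply(seq_along(spec$conc), function(i) {
    (rows - spec$centers[i, 1])^2 + (cols - spec$centers[i, 2])^2 <=
      spec$tube_radius^2
  })
}

#' Simulate a multi-tube glucose phantom acquisition
#'
#' Per tube, runs a water+glucose two-pool Bloch-McConnell simulation with the
#' tube T2 (shared Gd-shortened baseline plus the glucose relaxivity term),
#' rasterizes the tubes into the image grid, applies the multi-echo
#' \code{exp(-TE/T2)} decay and seeded noise.
#'
#' @param spec A [phantom_spec()].
#' @param pulse A [saturation_pulse()].
#' @param offsets Saturation offsets (ppm).
#' @param echo_train An [echo_train()].
#' @param seed Integer noise seed.
#' @param noise,snr Noise model and first-echo SNR (\code{"none"} to disable).
#' @param r2ex Glucose transverse relaxivity (s^-1 mM^-1).
#' @return List with \code{stack} (4D [multi_echo_stack()]:
#'   row, col, echo, offset), \code{unsat} (3D reference stack),
#'   \code{masks} (per-tube logical masks), and \code{truth}
#'   (per-tube T2 and the noiseless Z-spectra matrix offsets x tubes).
#' @export
make_phantom <- function(spec, pulse = saturation_pulse(2, 2),
                         offsets = seq(-5, 5, 0.2),
                         echo_train = NULL, seed = 1,
                         noise = "rician", snr = 50, r2ex = 0.053) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(echo_train)) echo_train <- default_echo_train()
  masks <- tube_masks(spec)
  t2_tube <- glucose_t2_ms(spec$conc, spec$t2_base, r2ex)
  sig <- vapply(seq_along(spec$conc), function(i) {
    pools <- list(
      water_pool(0.3, t2_tube[i] / 1000),
      exchange_pool("glucose", 1.2, glucose_fraction(spec$conc[i]), 4000,
                    1.0, 0.015))
    bmc_propagate(pools, pulse, offsets)$signal
  }, numeric(length(offsets)))
  te <- echo_train$te_eff
  g <- spec$grid
  sigma <- if (noise == "none") 0 else spec$pd * exp(-te[1] / spec$t2_base) / snr
  set.seed(as.integer(seed))
  data <- array(0, c(g, echo_train$n_echoes, length(offsets)))
  unsat <- array(0, c(g, echo_train$n_echoes))
  for (e in seq_along(te)) {
    plane0 <- matrix(0, g[1], g[2])
    for (i in seq_along(masks))
      plane0[masks[[i]]] <- spec$pd * exp(-te[e] / t2_tube[i])
    unsat[, , e] <- add_noise(plane0, sigma, noise)
    for (o in seq_along(offsets)) {
      plane <- matrix(0, g[1], g[2])
      for (i in seq_along(masks))
        plane[masks[[i]]] <- spec$pd * sig[o, i] * exp(-te[e] / t2_tube[i])
      data[, , e, o] <- add_noise(plane, sigma, noise)
    }
  }
  list(stack = multi_echo_stack(data, echo_train, offsets = offsets),
       unsat = multi_echo_stack(unsat, echo_train),
       masks = masks,
       truth = list(t2_ms = t2_tube, s = sig, offsets = offsets,
                    conc = spec$conc))
}

#' ROI DGE series from a simulated dynamic experiment
#'
#' Fits T2/PD maps frame by frame, normalizes against the unsaturated
#' reference and assembles the [dge_series()] and [dynamic_t2()] records at
#' the quantification offset. This is the measurement path a scanner
#' pipeline would follow; ground truth is not consulted.
#'
#' @param sim Output of [simulate_dge_experiment()].
#' @param offset Quantification offset (ppm).
#' @param method Fit method passed to [fit_t2_pd()].
#' @return List with \code{series} (a [dge_series()] with \code{mtr_asym}
#'   filled) and \code{t2} (a [dynamic_t2()] from the fitted maps).
#' @export
measure_dge_series <- function(sim, offset = 1.2, method = "nonlinear") {
  stack <- sim$stack
  p_off <- stack$offsets
  io_pos <- which(abs(p_off - offset) < 1e-9)
  io_neg <- which(abs(p_off + offset) < 1e-9)
  if (!length(io_pos) || !length(io_neg))
    stop("quantification offset +-", offset, " ppm not in the schedule")
  et <- stack$echo_train
  unsat_maps <- fit_t2_pd(sim$unsat, method = method)
  roi <- unsat_maps$mask
  ref <- mean(unsat_maps$pd[roi])
  nt <- dim(stack$data)[5]
  s_pos <- s_neg <- t2_hat <- numeric(nt)
  for (f in seq_len(nt)) {
    mp <- fit_t2_pd(multi_echo_stack(stack$data[, , , io_pos, f, drop = FALSE][, , , 1, 1],
                                     et), method = method)
    mn <- fit_t2_pd(multi_echo_stack(stack$data[, , , io_neg, f, drop = FALSE][, , , 1, 1],
                                     et), method = method)
    s_pos[f] <- mean(mp$pd[roi & mp$mask]) / ref
    s_neg[f] <- mean(mn$pd[roi & mn$mask]) / ref
    t2_hat[f] <- mean(mp$t2[roi & mp$mask])
  }
  bl <- sim$truth$baseline_idx
  series <- dge_series(sim$truth$time, s_pos, bl, offset = offset,
                       mtr_asym = s_neg - s_pos)
  series <- single_offset_dge(series)
  series <- mtr_asym_dge(series)
  list(series = series, t2 = dynamic_t2(sim$truth$time, t2_hat, bl))
}
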