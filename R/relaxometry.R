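# Voxel-wise mono-exponential T2 / saturation-weighted PD mapping of
# multi-echo magnitude stacks: S(TE) = PD * exp(-TE / T2). The log-linear
# solution seeds a vectorized Levenberg-damped Gauss-Newton refinement.

#' Echo train description
#'
#' @param n_echoes Number of echoes.
#' @param spacing Echo spacing (ms).
#' @param te_eff Nominal effective echo time per echo (ms); defaults to
#'   integer multiples of \code{spacing}. Arbitrary strictly increasing
#'   vectors are accepted.
#' @return Object of class \code{echo_train}.
#' @examples
#' echo_train()  # the 5 x 25 ms protocol
#' @export
echo_train <- function(n_echoes = 5, spacing = 25,
                       te_eff = seq_len(n_echoes) * spacing) {
  if (length(te_eff) != n_echoes) stop("te_eff length must equal n_echoes")
  if (any(diff(te_eff) <= 0)) stop("te_eff must be strictly increasing")
  structure(list(n_echoes = as.integer(n_echoes), spacing = spacing,
                 te_eff = as.numeric(te_eff)), class = "echo_train")
}

#' Multi-echo image stack
#'
#' Magnitude images indexed \code{(row, col, echo[, offset, time])} together
#' with the echo-time vector and optional offset / time metadata.
#'
#' @param data Numeric array, 3 to 5 dimensions, echo axis third.
#' @param echo_train An [echo_train()]; its length must match dim 3.
#' @param offsets Saturation offsets (ppm) for axis 4, or \code{NULL}.
#' @param time Acquisition times (s) for axis 5, or \code{NULL}.
#' @param mask Logical matrix over the spatial grid, or \code{NULL} (all
#'   voxels).
#' @return Object of class \code{multi_echo_stack}.
#' @export
multi_echo_stack <- function(data, echo_train, offsets = NULL, time = NULL,
                             mask = NULL) {
  stopifnot(inherits(echo_train, "echo_train"))
  d <- dim(data)
  if (is.null(d) || length(d) < 3L || length(d) > 5L)
    stop("data must have 3-5 dimensions (row, col, echo[, offset, time])")
  if (d[3] != echo_train$n_echoes)
    stop("echo axis length ", d[3], " != n_echoes ", echo_train$n_echoes)
  if (!is.null(offsets) && length(d) >= 4L && d[4] != length(offsets))
    stop("offset axis length ", d[4], " != length(offsets) ", length(offsets))
  if (!is.null(time) && length(d) == 5L && d[5] != length(time))
    stop("time axis length ", d[5], " != length(time) ", length(time))
  if (any(data < 0, na.rm = TRUE)) stop("magnitude data must be >= 0")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!all(dim(mask) == d[1:2])) stop("mask shape must match spatial grid")
  structure(list(data = data, echo_train = echo_train, offsets = offsets,
                 time = time, mask = mask), class = "multi_echo_stack")
}

#' @export
print.multi_echo_stack <- function(x, ...) {
  cat("<multi-echo stack> dims:", paste(dim(x$data), collapse = " x "),
      " te:", paste(x$echo_train$te_eff, collapse = "/"), "ms\n")
  if (!is.null(x$offsets)) cat("  offsets:", paste(x$offsets, collapse = ", "), "ppm\n")
  if (!is.null(x$time)) cat("  time:", length(x$time), "frames\n")
  invisible(x)
}

# Default mask: drop noise-floor voxels whose first-echo intensity is below
# 5% of the image's 99th percentile.
default_mask <- function(first_echo, frac = 0.05) {
  thr <- frac * stats::quantile(first_echo, 0.99, na.rm = TRUE)
  is.finite(first_echo) & first_echo > thr
}

# Vectorized fit of S = A exp(-te R) on a voxel x echo matrix.
# Returns list(pd, t2_ms, r2fit) with NA where the fit is invalid.
fit_exp_matrix <- function(V, te, method = "nonlinear", weighted = FALSE,
                           max_iter = 200L, rel_tol = 1e-8) {
  nv <- nrow(V)
  ok <- rowSums(is.finite(V) & V > 0) >= 2L
  pd <- t2 <- q <- rep(NA_real_, nv)
  if (!any(ok)) return(list(pd = pd, t2_ms = t2, fit_quality = q, valid = ok))
  W <- V[ok, , drop = FALSE]
  W[!(is.finite(W) & W > 0)] <- NA
  L <- log(W)
  # closed-form per-voxel weighted linear regression of log S on te.
  # Weighting by S^2 approximates homoscedastic errors in the linear domain.
  wt <- if (weighted) W^2 else (!is.na(W)) * 1
  wt[is.na(W)] <- 0
  L0 <- L; L0[is.na(L)] <- 0
  sw <- rowSums(wt)
  mx <- rowSums(wt * rep(te, each = nrow(W))) / sw
  my <- rowSums(wt * L0) / sw
  tec <- sweep(matrix(te, nrow(W), length(te), byrow = TRUE), 1, mx)
  sxx <- rowSums(wt * tec^2)
  sxy <- rowSums(wt * tec * (L0 - my * (wt > 0)))
  slope <- sxy / sxx
  A <- exp(my - slope * mx)
  R <- -slope                                   # 1/ms
  bad <- !is.finite(R) | R <= 0 | !is.finite(A)
  R[bad] <- 1 / max(te); A[bad] <- rowMeans(W, na.rm = TRUE)[bad]
  if (method == "nonlinear") {
    lambda <- rep(1e-3, nrow(W))
    Wz <- W; Wz[is.na(W)] <- 0
    msk <- (!is.na(W)) * 1
    sse <- function(A, R) {
      E <- exp(-outer(R, te))
      rowSums(msk * (A * E - Wz)^2)
    }
    f0 <- sse(A, R)
    for (it in seq_len(max_iter)) {
      E <- exp(-outer(R, te))
      r <- msk * (A * E - Wz)
      J1 <- msk * E
      J2 <- msk * (-A * E * rep(te, each = nrow(W)))
      g1 <- rowSums(J1 * r); g2 <- rowSums(J2 * r)
      h11 <- rowSums(J1^2); h22 <- rowSums(J2^2); h12 <- rowSums(J1 * J2)
      d11 <- h11 * (1 + lambda); d22 <- h22 * (1 + lambda)
      det <- d11 * d22 - h12^2
      dA <- (d22 * g1 - h12 * g2) / det
      dR <- (d11 * g2 - h12 * g1) / det
      A1 <- A - dA; R1 <- R - dR
      fixup <- !is.finite(A1) | !is.finite(R1) | R1 <= 0 | A1 <= 0
      A1[fixup] <- A[fixup]; R1[fixup] <- R[fixup]
      f1 <- sse(A1, R1)
      acc <- f1 <= f0
      lambda <- ifelse(acc, pmax(lambda / 3, 1e-12), pmin(lambda * 5, 1e8))
      step <- pmax(abs(A1 - A) / pmax(abs(A), 1e-12),
                   abs(R1 - R) / pmax(abs(R), 1e-12))
      A <- ifelse(acc, A1, A); R <- ifelse(acc, R1, R)
      f0 <- ifelse(acc, f1, f0)
      if (max(step[acc], 0) < rel_tol) break
    }
  }
  E <- exp(-outer(R, te))
  msk <- (!is.na(W)) * 1
  Wz <- W; Wz[is.na(W)] <- 0
  resid <- rowSums(msk * (A * E - Wz)^2)
  tot <- rowSums(msk * (Wz - rowSums(msk * Wz) / rowSums(msk))^2)
  qual <- pmin(pmax(1 - resid / pmax(tot, .Machine$double.eps), 0), 1)
  pd[ok] <- A; t2[ok] <- 1 / R; q[ok] <- qual
  invalid <- ok
  invalid[ok] <- !is.finite(A) | !is.finite(R) | R <= 0
  pd[invalid] <- NA; t2[invalid] <- NA; q[invalid] <- NA
  list(pd = pd, t2_ms = t2, fit_quality = q, valid = ok & !invalid)
}

#' Fit T2 and saturation-weighted PD maps from a multi-echo stack
#'
#' Voxel-wise mono-exponential fit \code{S(TE) = PD exp(-TE/T2)}. The
#' nonlinear mode (default) runs a damped Gauss-Newton refinement initialized
#' from the log-linear solution; the log-linear mode returns that solution
#' directly. Voxels outside the mask or with fewer than two positive echo
#' samples are flagged invalid.
#'
#' @param stack A [multi_echo_stack()] with a 3D \code{(row, col, echo)} data
#'   array (higher-dimensional stacks: fit one sub-volume at a time, see
#'   [pd_zspectrum()]).
#' @param method \code{"nonlinear"} or \code{"loglinear"}.
#' @param mask Logical matrix; defaults to the stack mask intersected with a
#'   noise-floor mask (first-echo intensity above 5\% of the 99th percentile).
#' @param weighted Weight the log-linear stage by squared signal (approximate
#'   inverse-variance in the log domain). Default \code{FALSE}.
#' @return Object of class \code{parameter_maps}: list with matrices
#'   \code{pd}, \code{t2} (ms), \code{fit_quality} in [0, 1], and logical
#'   \code{mask} of successfully fitted voxels.
#' @examples
#' et <- echo_train()
#' img <- array(1000 * exp(-rep(et$te_eff, each = 4) / 44.3), c(2, 2, 5))
#' maps <- fit_t2_pd(multi_echo_stack(img, et))
#' maps$t2[1, 1]
#' @export
fit_t2_pd <- function(stack, method = c("nonlinear", "loglinear"),
                      mask = NULL, weighted = FALSE) {
  stopifnot(inherits(stack, "multi_echo_stack"))
  method <- match.arg(method)
  d <- dim(stack$data)
  if (length(d) != 3L)
    stop("fit_t2_pd expects a 3D (row, col, echo) array; got ",
         length(d), "D")
  te <- stack$echo_train$te_eff
  first <- stack$data[, , 1]
  m <- stack$mask & default_mask(first)
  if (!is.null(mask)) m <- m & mask
  V <- matrix(stack$data, nrow = d[1] * d[2], ncol = d[3])
  V[!as.vector(m), ] <- NA
  fit <- fit_exp_matrix(V, te, method = method, weighted = weighted)
  if (!any(fit$valid)) stop("no valid voxels to fit")
  shape <- function(v) matrix(v, d[1], d[2])
  structure(list(pd = shape(fit$pd), t2 = shape(fit$t2_ms),
                 fit_quality = shape(fit$fit_quality),
                 mask = shape(fit$valid)),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("<parameter maps> %d x %d, %d valid voxels; median T2 = %.1f ms\n",
              nrow(x$t2), ncol(x$t2), sum(x$mask),
              stats::median(x$t2[x$mask])))
  invisible(x)
}

#' Z-spectrum from saturation-weighted PD maps
#'
#' Normalizes per-offset saturation-weighted PD against the unsaturated PD:
#' \code{S(offset) = PD_sat(offset) / PD_unsat}. Using the echo-fit amplitude
#' rather than a single T2-weighted echo removes the T2-decay modulation of
#' the readout from the Z-spectrum.
#'
#' @param maps_per_offset List of [fit_t2_pd()] results, one per offset.
#' @param unsaturated [fit_t2_pd()] result for the unsaturated reference.
#' @param offsets Offsets (ppm) matching \code{maps_per_offset}.
#' @param roi Logical matrix; when supplied, voxel PD values are averaged over
#'   the ROI before the ratio (ROI mode) and a single [z_spectrum()] is
#'   returned. Without it a \code{(row, col, offset)} array of voxel spectra
#'   is returned.
#' @return A [z_spectrum()] (ROI mode) or a 3D array.
#' @export
pd_zspectrum <- function(maps_per_offset, unsaturated, offsets, roi = NULL) {
  stopifnot(length(maps_per_offset) == length(offsets))
  g <- dim(unsaturated$pd)
  for (mp in maps_per_offset)
    if (!all(dim(mp$pd) == g)) stop("all maps must share one grid")
  if (!is.null(roi)) {
    m <- roi & unsaturated$mask
    ref <- mean(unsaturated$pd[m])
    if (!is.finite(ref) || ref <= 0) stop("invalid unsaturated reference in ROI")
    sig <- vapply(maps_per_offset,
                  function(mp) mean(mp$pd[m & mp$mask]) / ref, numeric(1))
    return(z_spectrum(offsets, sig))
  }
  out <- array(NA_real_, c(g, length(offsets)))
  denom <- unsaturated$pd
  denom[!unsaturated$mask | denom <= 0] <- NA
  for (i in seq_along(offsets)) {
    num <- maps_per_offset[[i]]$pd
    num[!maps_per_offset[[i]]$mask] <- NA
    out[, , i] <- num / denom
  }
  out
}

#' Full width at half maximum of the Z-spectrum dip
#'
#' Width of the saturation dip at half depth between its minimum and the
#' far-offset baseline (mean of the two spectrum edges), with linear
#' interpolation of the crossings.
#'
#' @param z A [z_spectrum()].
#' @return Width (ppm).
#' @export
spectrum_fwhm <- function(z) {
  s <- z$signal; o <- z$offset_ppm
  if (is.unsorted(o)) { idx <- order(o); s <- s[idx]; o <- o[idx] }
  imin <- which.min(s)
  base <- mean(c(s[1], s[length(s)]))
  depth <- base - s[imin]
  if (imin == 1L || imin == length(s) || depth <= 1e-9 * max(abs(base), 1))
    stop("no interior saturation dip: FWHM undefined")
  half <- s[imin] + depth / 2
  cross <- function(idx_side) {
    below <- s[idx_side] <= half
    if (!any(below) || !any(!below)) stop("half level not bracketed: FWHM undefined")
    # last transition adjacent to the minimum
    tr <- which(diff(below) != 0)
    i <- idx_side[tr[if (idx_side[1] < imin) length(tr) else 1L]]
    j <- i + 1L
    o[i] + (half - s[i]) * (o[j] - o[i]) / (s[j] - s[i])
  }
  left <- cross(seq_len(imin))
  right <- cross(seq(imin, length(s)))
  right - left
}

default_echo_train <- function() echo_train(5, 25)
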