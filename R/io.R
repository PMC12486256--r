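# Stack / spectrum / table I/O: NIfTI images with JSON sidecars, CSV tables
# with '#' metadata headers, YAML/JSON configuration files.

#' Write a multi-echo stack as NIfTI plus JSON sidecar
#'
#' The image goes to \code{<path>} and the metadata (echo times, offsets,
#' frame times) to the matching \code{.json} sidecar.
#'
#' @param stack A [multi_echo_stack()].
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "multi_echo_stack"))
  write_nifti(stack$data, path)
  side <- list(te_ms = stack$echo_train$te_eff,
               echo_spacing_ms = stack$echo_train$spacing)
  if (!is.null(stack$offsets)) side$offsets_ppm <- stack$offsets
  if (!is.null(stack$time)) side$time_s <- stack$time
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a multi-echo stack written by [write_stack()]
#'
#' Validates the sidecar metadata against the array shape: the echo axis must
#' match \code{te_ms}, and the offset/time axes (when present) must match
#' \code{offsets_ppm} / \code{time_s}.
#'
#' @param path Path to the \code{.nii} / \code{.nii.gz} file.
#' @return A [multi_echo_stack()].
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$te_ms)) stop(sc, ": sidecar lacks required key 'te_ms'")
  data <- read_nifti(path)
  d <- dim(data)
  if (length(d) < 3)
    stop(path, ": ", length(d), "D image has no echo axis (need row, col, echo)")
  if (d[3] != length(meta$te_ms))
    stop(path, ": echo axis length ", d[3], " does not match ",
         length(meta$te_ms), " te_ms sidecar values")
  et <- echo_train(length(meta$te_ms),
                   spacing = meta$echo_spacing_ms %||% diff(meta$te_ms)[1],
                   te_eff = meta$te_ms)
  multi_echo_stack(data, et, offsets = meta$offsets_ppm, time = meta$time_s)
}

#' Write a Z-spectrum (or any small table) as CSV with metadata header
#'
#' Comma-separated, '.' decimal; metadata lines are prefixed with '#'.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param meta Named list written as \code{# key: value} header lines.
#' @return \code{path}, invisibly.
#' @export
write_csv_meta <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_csv_meta
#' @export
read_csv_meta <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Read a pool/pulse configuration file
#'
#' YAML or JSON (by extension) with the schema:
#' \preformatted{
#' pulse: {b1_uT: 2, tsat_s: 2, offset_ppm: 1.2, b0_T: 7}
#' pools:
#'   - {name: water, delta_ppm: 0, fraction: 1, k_ex: 0, T1: 1.8, T2: 0.0443}
#'   - {name: glucose, delta_ppm: 1.2, fraction: 9e-4, k_ex: 4000, T1: 1, T2: 0.015}
#' }
#'
#' @param path Path to a \code{.yaml}/\code{.yml}/\code{.json} file.
#' @return List with \code{pools} (list of [exchange_pool()]) and
#'   \code{pulse} (a [saturation_pulse()], or \code{NULL} if absent).
#' @export
read_pool_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$pools)) stop(path, ": config lacks 'pools'")
  as_row_list <- function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    else x
  }
  pools <- lapply(as_row_list(cfg$pools), function(p) {
    exchange_pool(p$name, p$delta_ppm, p$fraction, p$k_ex, p$T1, p$T2)
  })
  pulse <- NULL
  if (!is.null(cfg$pulse)) {
    pp <- cfg$pulse
    pulse <- saturation_pulse(pp$b1_uT, pp$tsat_s,
                              offset = pp$offset_ppm %||% 1.2,
                              b0 = pp$b0_T %||% 7)
  }
  list(pools = pool_system(pools), pulse = pulse)
}

#' Save / load a calibrated correction model as JSON
#'
#' The JSON round trip is bit-exact (full double precision).
#'
#' @param model A [correction_model()].
#' @param path Output path.
#' @return \code{write_correction_model}: \code{path} invisibly;
#'   \code{read_correction_model}: the model.
#' @export
write_correction_model <- function(model, path) {
  stopifnot(inherits(model, "correction_model"))
  payload <- unclass(model)
  payload$version <- as.character(utils::packageVersion("mpcest"))
  # digits = I(17): shortest-exact decimal would lose the last ulp here
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- correction_model(k = x$k %||% NA_real_, a = x$a %||% NA_real_,
                        b = x$b %||% NA_real_, c = x$c %||% NA_real_,
                        t2_ref = x$t2_ref, s0 = x$s0 %||% NA_real_,
                        scale = x$scale %||% NA_real_,
                        calib = x$calib %||% list())
  m
}

#' Export a DGE series (with any corrections) as CSV
#'
#' @param series A [dge_series()].
#' @param path Output path.
#' @param meta Extra metadata for the '#' header.
#' @return \code{path}, invisibly.
#' @export
write_dge_series <- function(series, path, meta = list()) {
  stopifnot(inherits(series, "dge_series"))
  df <- data.frame(time_s = series$time, offset_ppm = series$offset,
                   S = series$signal)
  for (col in c("dge", "dge_corrected", "mtr_asym", "dge_asym",
                "dge_asym_corrected")) {
    if (!is.null(series[[col]])) df[[sub("^dge$", "dge_pct", col)]] <- series[[col]]
  }
  meta$baseline_frames <- length(series$baseline_idx)
  write_csv_meta(df, path, meta)
}
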