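# Minimal NIfTI-1 single-file (.nii / .nii.gz) float32 reader/writer.
# No NIfTI package ships with this toolchain, and the format's fixed 348-byte
# header makes a self-contained codec the lightest dependency-free option.
# Only the fields this package needs are honoured: dim, datatype (float32,
# float64, int16, uint16), pixdim, scl_slope/inter, vox_offset.

NIFTI_DT <- list(`4` = list(what = "integer", size = 2, signed = TRUE),
                 `16` = list(what = "numeric", size = 4),
                 `64` = list(what = "numeric", size = 8),
                 `512` = list(what = "integer", size = 2, signed = FALSE))

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write an array as a NIfTI-1 image
#'
#' Single-file little-endian NIfTI-1 with float32 storage. Gzip compression is
#' chosen from the file extension (\code{.nii.gz}).
#'
#' @param data Numeric array (up to 7 dimensions).
#' @param path Output path ending in \code{.nii} or \code{.nii.gz}.
#' @param pixdim Voxel dimensions, recycled/padded to 7 values.
#' @return \code{path}, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = rep(1, 7)) {
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  if (length(d) > 7) stop("NIfTI supports at most 7 dimensions")
  con <- nii_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  dims <- c(length(d), d, rep(1L, 7 - length(d)))
  wi(dims, 2)                                   # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1..p3, intent_code
  wi(16L, 2)                                    # datatype = float32
  wi(32L, 2)                                    # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(0, pixdim[seq_len(7)]))                  # pixdim[8] (qfac 0)
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                             # cal_max..toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip, aux_file
  wi(c(0L, 0L), 2)                              # qform, sform codes
  wf(rep(0, 18))                                # quatern + srow
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @return Numeric array with the on-disk dimensions.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop(path, ": truncated NIfTI header")
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n, size, endian = "little")
  rf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)],
                                 "numeric", n, size = 4, endian = "little")
  if (ri(0, 1, 4) != 348L) stop(path, ": not a NIfTI-1 file")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop(path, ": unsupported NIfTI magic '", magic, "'")
  dims <- ri(40, 8, 2)
  d <- dims[2:(1 + dims[1])]
  dt <- as.character(ri(70, 1, 2))
  spec <- NIFTI_DT[[dt]]
  if (is.null(spec)) stop(path, ": unsupported datatype code ", dt)
  vox_offset <- rf(108, 1)
  slope <- rf(112, 1); inter <- rf(116, 1)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  vals <- readBin(con, spec$what, n, size = spec$size, endian = "little",
                  signed = if (is.null(spec$signed)) TRUE else spec$signed)
  if (length(vals) < n) stop(path, ": truncated voxel data")
  if (slope != 0 && !(slope == 1 && inter == 0)) vals <- vals * slope + inter
  array(vals, dim = d)
}
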