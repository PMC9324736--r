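# Minimal NIfTI-1 single-file (.nii / .nii.gz) codec.
#
# No NIfTI package ships with this environment, so the subset of the format
# the pipeline needs is implemented directly: one 3D image per file,
# datatypes uint8/int16/int32/uint16/float32/float64, little- or big-endian
# on read, little-endian on write, sform affine carried through, no
# extensions. This is deliberately not a general NIfTI library.

NIFTI_DT <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "double",  size = 8L, signed = TRUE),
  uint16  = list(code = 512L, bitpix = 16L, what = "integer", size = 2L, signed = FALSE)
)

nifti_dt_by_code <- function(code) {
  for (nm in names(NIFTI_DT)) if (NIFTI_DT[[nm]]$code == code) return(NIFTI_DT[[nm]])
  stop(sprintf("unsupported NIfTI datatype code %d", code), call. = FALSE)
}

read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop(sprintf("not a NIfTI-1 file (truncated header): %s", path), call. = FALSE)

  rd <- function(raw, what, n, size, offset, endian, signed = TRUE) {
    readBin(raw[(offset + 1):(offset + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd(hdr, "integer", 1L, 4L, 0L, endian) != 348L) {
    endian <- "big"
    if (rd(hdr, "integer", 1L, 4L, 0L, endian) != 348L) {
      stop(sprintf("not a NIfTI-1 file (bad sizeof_hdr): %s", path), call. = FALSE)
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop(sprintf("not a NIfTI-1 file (bad magic '%s'): %s", magic, path), call. = FALSE)
  }
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported", call. = FALSE)

  dim8 <- rd(hdr, "integer", 8L, 2L, 40L, endian)
  ndim <- dim8[1]
  if (ndim < 3L || ndim > 4L || (ndim == 4L && dim8[5] != 1L)) {
    stop("only 3D NIfTI volumes are supported", call. = FALSE)
  }
  dims <- dim8[2:4]
  datatype <- rd(hdr, "integer", 1L, 2L, 70L, endian)
  dt <- nifti_dt_by_code(datatype)
  pixdim <- rd(hdr, "double", 8L, 4L, 76L, endian)
  vox_offset <- rd(hdr, "double", 1L, 4L, 108L, endian)
  scl_slope <- rd(hdr, "double", 1L, 4L, 112L, endian)
  scl_inter <- rd(hdr, "double", 1L, 4L, 116L, endian)
  sform_code <- rd(hdr, "integer", 1L, 2L, 254L, endian)
  srow <- matrix(rd(hdr, "double", 12L, 4L, 280L, endian), nrow = 3L, byrow = TRUE)

  # gz connections cannot seek reliably; consume up to the data offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) invisible(readBin(con, "raw", n = skip))

  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) != n) stop(sprintf("truncated NIfTI data in %s", path), call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- as.double(vals) * scl_slope + scl_inter
  }
  arr <- array(vals, dim = dims)

  affine <- NULL
  if (sform_code > 0L) affine <- rbind(srow, c(0, 0, 0, 1))
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  volume3d(arr, spacing = spacing, affine = affine)
}

write_nifti <- function(vol, path, datatype = "auto") {
  arr <- as_array3d(vol)
  if (identical(datatype, "auto")) {
    datatype <- if (is.integer(arr)) "int32" else "float64"
  }
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) {
    stop(sprintf("unsupported datatype '%s' (use one of: %s)", datatype,
                 paste(names(NIFTI_DT), collapse = ", ")), call. = FALSE)
  }
  dims <- dim(arr)
  spacing <- attr(vol, "spacing") %||% c(1, 1, 1)
  affine <- attr(vol, "affine")

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)

  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4L)                               # sizeof_hdr
  wraw(36L)                                  # data_type..regular, dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)        # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)                 # intent_p1..3, intent_code
  wi(dt$code, 2L); wi(dt$bitpix, 2L)         # datatype, bitpix
  wi(0L, 2L)                                 # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))              # pixdim[8]
  wf(352)                                    # vox_offset
  wf(1); wf(0)                               # scl_slope, scl_inter
  wi(0L, 2L); wraw(2L)                       # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                          # glmax, glmin
  wraw(104L)                                 # descrip[80] + aux_file[24]
  wi(0L, 2L)                                 # qform_code
  wi(if (is.null(affine)) 0L else 1L, 2L)    # sform_code
  wf(rep(0, 6))                              # quatern b,c,d + qoffset x,y,z
  if (is.null(affine)) {
    wf(rep(0, 12))
  } else {
    wf(as.double(t(affine[1:3, ])))          # srow_x, srow_y, srow_z
  }
  wraw(16L)                                  # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
  wraw(4L)                                   # extension indicator

  if (dt$what == "integer") {
    v <- round(as.double(arr))
    lo <- if (dt$signed) -(2^(dt$bitpix - 1)) else 0
    hi <- if (dt$signed) 2^(dt$bitpix - 1) - 1 else 2^dt$bitpix - 1
    if (any(v < lo | v > hi)) {
      stop(sprintf("values out of range for %s storage", datatype), call. = FALSE)
    }
    if (!dt$signed && dt$size < 4L) {
      # writeBin stores signed ints at size < 4; fold into two's complement
      v <- ifelse(v > 2^(dt$bitpix - 1) - 1, v - 2^dt$bitpix, v)
    }
    writeBin(as.integer(v), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(arr), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
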