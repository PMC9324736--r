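# Minimal DICOM series reader.
#
# Supports the common on-disk case for MR exports: part-10 files (128-byte
# preamble + "DICM"), explicit-VR little-endian transfer syntax, one
# uncompressed monochrome frame per file. Slices are ordered by
# ImagePositionPatient along the slice normal (InstanceNumber as fallback),
# never by file name. Anything fancier (compressed pixel data, implicit VR,
# big-endian, multiframe) is rejected with a format error.

dicom_read_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM") {
    stop(sprintf("not a part-10 DICOM file: %s", path), call. = FALSE)
  }
  pos <- 132L  # 0-based offset of the next byte to read
  n <- length(raw)

  u16 <- function(at) {
    as.integer(raw[at + 1L]) + 256L * as.integer(raw[at + 2L])
  }
  u32 <- function(at) {
    as.integer(raw[at + 1L]) + 256 * as.integer(raw[at + 2L]) +
      65536 * as.integer(raw[at + 3L]) + 16777216 * as.integer(raw[at + 4L])
  }

  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  el <- list()
  pixel <- NULL
  pixel_len <- NA_integer_

  while (pos + 8L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 5L):(pos + 6L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop(sprintf("implicit-VR or corrupt DICOM element at offset %d in %s", pos, path),
           call. = FALSE)
    }
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      body <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      body <- pos + 8L
    }
    if (len == 4294967295 || (vr == "SQ")) {
      stop(sprintf("unsupported DICOM element (SQ/undefined length) in %s", path),
           call. = FALSE)
    }
    if (body + len > n) stop(sprintf("truncated DICOM element in %s", path), call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "7fe0,0010") {
      pixel <- raw[(body + 1L):(body + len)]
      pixel_len <- len
      pos <- body + len
      next
    }
    bytes <- if (len > 0L) raw[(body + 1L):(body + len)] else raw(0)
    el[[key]] <- switch(vr,
      US = readBin(bytes, "integer", n = len / 2L, size = 2L,
                   endian = "little", signed = FALSE),
      UL = readBin(bytes, "integer", n = len / 4L, size = 4L, endian = "little"),
      SS = readBin(bytes, "integer", n = len / 2L, size = 2L, endian = "little"),
      SL = readBin(bytes, "integer", n = len / 4L, size = 4L, endian = "little"),
      FL = readBin(bytes, "double", n = len / 4L, size = 4L, endian = "little"),
      FD = readBin(bytes, "double", n = len / 8L, size = 8L, endian = "little"),
      DS = as.numeric(strsplit(trimws(rawToChar(bytes)), "\\\\")[[1]]),
      IS = as.integer(strsplit(trimws(rawToChar(bytes)), "\\\\")[[1]]),
      trimws(rawToChar(bytes))
    )
    pos <- body + len
  }

  rows <- el[["0028,0010"]]; cols <- el[["0028,0011"]]
  bits <- el[["0028,0100"]] %||% 16L
  pixrep <- el[["0028,0103"]] %||% 0L
  if (is.null(rows) || is.null(cols) || is.null(pixel)) {
    stop(sprintf("DICOM file lacks image pixel module: %s", path), call. = FALSE)
  }
  if (!bits %in% c(8L, 16L)) {
    stop(sprintf("unsupported BitsAllocated=%d in %s", bits, path), call. = FALSE)
  }
  npix <- as.integer(rows) * as.integer(cols)
  if (pixel_len < npix * (bits / 8L)) {
    stop(sprintf("pixel data shorter than Rows*Columns in %s", path), call. = FALSE)
  }
  vals <- readBin(pixel, "integer", n = npix, size = bits / 8L, endian = "little",
                  signed = (pixrep == 1L && bits == 16L))
  slope <- el[["0028,1053"]] %||% 1
  inter <- el[["0028,1052"]] %||% 0
  v <- as.double(vals) * slope + inter
  # DICOM pixel order is row-major; build (row, col)
  img <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)

  list(
    image = img,
    position = el[["0020,0032"]],
    orientation = el[["0020,0037"]],
    instance = el[["0020,0013"]],
    pixel_spacing = el[["0028,0030"]],
    slice_thickness = el[["0018,0050"]],
    series_uid = el[["0020,000e"]]
  )
}

read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("directory not found: %s", dir), call. = FALSE)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop(sprintf("no files in DICOM directory: %s", dir), call. = FALSE)
  slices <- lapply(files, dicom_read_file)

  shapes <- vapply(slices, function(s) paste(dim(s$image), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop(sprintf("inconsistent DICOM series in %s: mixed slice shapes (%s)",
                 dir, paste(unique(shapes), collapse = ", ")), call. = FALSE)
  }
  orients <- vapply(slices, function(s) paste(signif(s$orientation %||% NA, 6), collapse = ","), "")
  if (length(unique(orients)) != 1L) {
    stop(sprintf("inconsistent DICOM series in %s: mixed orientations", dir), call. = FALSE)
  }

  # sort by position projected on the slice normal; fall back to InstanceNumber
  ord <- seq_along(slices)
  pos_ok <- all(vapply(slices, function(s) length(s$position) == 3L, TRUE))
  if (pos_ok) {
    orient <- slices[[1]]$orientation
    normal <- if (length(orient) == 6L) {
      r <- orient[1:3]; c <- orient[4:6]
      c(r[2] * c[3] - r[3] * c[2], r[3] * c[1] - r[1] * c[3], r[1] * c[2] - r[2] * c[1])
    } else c(0, 0, 1)
    proj <- vapply(slices, function(s) sum(s$position * normal), 0)
    ord <- order(proj)
  } else if (all(vapply(slices, function(s) length(s$instance) == 1L, TRUE))) {
    ord <- order(vapply(slices, function(s) s$instance[1], 0L))
  }
  slices <- slices[ord]

  d2 <- dim(slices[[1]]$image)
  arr <- array(0, dim = c(length(slices), d2[1], d2[2]))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]$image

  ps <- slices[[1]]$pixel_spacing %||% c(1, 1)
  st <- slices[[1]]$slice_thickness %||% 1
  volume3d(arr, spacing = c(st, ps[1], ps[2]))
}
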