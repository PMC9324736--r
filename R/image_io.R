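#' Read an image volume
#'
#' Reads a 3D volume from a NIfTI-1 file (`.nii` / `.nii.gz`) or a DICOM
#' series directory. Voxel index order in the returned array is
#' (slice, row, column); intensities and orientation metadata are carried
#' through unchanged.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"`, `"dicom"`, or `"auto"` (directory implies DICOM,
#'   otherwise NIfTI).
#' @return A [volume3d()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "dicom" else "nifti"
  if (!file.exists(path) && !dir.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  switch(format, nifti = read_nifti(path), dicom = read_dicom_series(path))
}

#' Write an image volume
#'
#' Writes a [volume3d()] (or bare 3D array) as NIfTI-1. Integer arrays are
#' stored as int32, doubles as float64, so a write/read round trip is exact.
#' DICOM writing is intentionally not supported.
#'
#' @param vol a [volume3d()] or 3D array; must be finite and non-negative.
#' @param path output path; a `.gz` suffix enables gzip compression.
#' @param format only `"nifti"`.
#' @param datatype storage type: `"auto"`, `"uint8"`, `"int16"`, `"int32"`,
#'   `"uint16"`, `"float32"`, or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = "nifti", datatype = "auto") {
  if (!identical(format, "nifti")) {
    stop("only NIfTI writing is supported", call. = FALSE)
  }
  if (!inherits(vol, "volume3d")) vol <- volume3d(vol)  # validates finiteness
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
  write_nifti(vol, path, datatype = datatype)
  invisible(path)
}

#' Write a label mask as integer NIfTI
#'
#' @param mask a [label_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  arr <- array(as.integer(mask), dim = dim(mask))
  write_nifti(volume3d(arr), path, datatype = "int16")
  invisible(path)
}

#' Read a label mask from integer NIfTI
#'
#' @param path NIfTI file with integer labels.
#' @param legend label legend, see [label_mask()].
#' @return A [label_mask()].
#' @export
read_mask <- function(path, legend = c(background = 0L, pca = 1L, pz = 2L, tz = 3L)) {
  vol <- read_nifti(path)
  label_mask(array(as.integer(round(as_array3d(vol))), dim = dim(vol)), legend = legend)
}

#' Export a raster to an 8-bit PNG
#'
#' Values must lie in \[0, 1\]; they are quantized by round-half-up to
#' 0–255 (so 0.5 maps to pixel value 128).
#'
#' @param map_raster 2D grayscale matrix or row x col x 3 RGB array in \[0,1\].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
export_map_image <- function(map_raster, path) {
  if (!(is.matrix(map_raster) ||
        (is.array(map_raster) && length(dim(map_raster)) == 3L && dim(map_raster)[3] == 3L))) {
    stop("`map_raster` must be a 2D gray matrix or an RGB array", call. = FALSE)
  }
  if (anyNA(map_raster) || any(map_raster < 0) || any(map_raster > 1)) {
    stop("raster values must lie in [0, 1]", call. = FALSE)
  }
  q <- floor(unclass(map_raster) * 255 + 0.5) / 255  # round half up, then exact /255
  png::writePNG(q, target = path)
  invisible(path)
}
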