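#' 3D image volume
#'
#' A `volume3d` is a plain 3D numeric array with voxel index order
#' (slice, row, column) plus spacing and orientation metadata. All
#' intensities must be finite and non-negative; volumes combined in one
#' pipeline run must share a shape.
#'
#' @param voxels 3D numeric array, index order (slice, row, column).
#' @param spacing numeric length-3, mm per axis (slice, row, column).
#' @param affine optional 4x4 voxel-to-world matrix; preserved opaquely on
#'   file round trips.
#' @return A `volume3d` object.
#' @export
volume3d <- function(voxels, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array (slice, row, column)", call. = FALSE)
  }
  storage.mode(voxels) <- if (is.integer(voxels)) "integer" else "double"
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    stop("volume intensities must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(voxels < 0)) {
    stop("volume intensities must be non-negative", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  }
  if (!is.null(affine)) {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4", call. = FALSE)
  }
  structure(voxels, spacing = spacing, affine = affine, class = c("volume3d", class(voxels)))
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<volume3d> %d x %d x %d (slice x row x col), spacing %s mm, range [%g, %g]\n",
    d[1], d[2], d[3], paste(signif(attr(x, "spacing"), 4), collapse = " x "),
    min(x), max(x)
  ))
  invisible(x)
}

# strip class/attrs down to a bare array
as_array3d <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x))
  a
}

#' Multi-class segmentation mask
#'
#' Integer-label volume sharing the shape of its associated [volume3d()].
#' The default legend follows the prostate convention: 0 background,
#' 1 tumor (PCa), 2 peripheral zone (PZ), 3 transitional/central zone (TZ).
#'
#' @param labels 3D integer array (slice, row, column).
#' @param legend named integer vector mapping class names to label values.
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels,
                       legend = c(background = 0L, pca = 1L, pz = 2L, tz = 3L)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  if (anyNA(labels)) stop("mask labels must not contain NA", call. = FALSE)
  lv <- as.integer(labels)
  if (any(lv != as.numeric(labels))) stop("mask labels must be integers", call. = FALSE)
  if (!all(unique(lv) %in% legend)) {
    stop("mask contains label values absent from the legend", call. = FALSE)
  }
  arr <- array(lv, dim = dim(labels))
  structure(arr, legend = legend, class = c("label_mask", class(arr)))
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x)
  tab <- table(factor(as.integer(x), levels = attr(x, "legend")))
  names(tab) <- names(attr(x, "legend"))
  cat(sprintf("<label_mask> %d x %d x %d\n", d[1], d[2], d[3]))
  print(tab)
  invisible(x)
}

mask_legend <- function(mask) attr(mask, "legend")

# resolve a legend entry given by name or integer value
resolve_label <- function(mask, label) {
  legend <- mask_legend(mask)
  if (is.character(label)) {
    if (!label %in% names(legend)) {
      stop(sprintf("unknown class '%s'; legend has: %s", label,
                   paste(names(legend), collapse = ", ")), call. = FALSE)
    }
    unname(legend[[label]])
  } else {
    label <- as.integer(label)
    if (!label %in% legend) {
      stop(sprintf("label %d is not in the mask legend", label), call. = FALSE)
    }
    label
  }
}

stopifnot_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share one shape (got %s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
}
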