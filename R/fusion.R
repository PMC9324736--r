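# Fusion: the reverse lookup. Every voxel's (adc_norm, dwi_norm) coordinate
# indexes the intensity map and the looked-up gray (or RGB) value is plotted
# back onto the voxel location, yielding the multichannel computed diffusion
# image (mcDI).

#' Fuse a normalized pair into an mcDI
#'
#' Evaluates `map` at every voxel's (adc_norm, dwi_norm) coordinate. With
#' the level-1 map the result is exactly `adc_norm`; with a 90-degree,
#' zero-suppression map it is exactly `1 - dwi_norm`.
#'
#' @param pair a [normalized_pair()].
#' @param map an [intensity_map()].
#' @return An `mcdi_volume`: 3D array in \[0,1\] (gray mode) or a
#'   slice x row x col x 3 array (color mode), with the map parameters
#'   attached as `params`.
#' @export
fuse <- function(pair, map) {
  if (!inherits(pair, "normalized_pair")) stop("`pair` must be a normalized_pair", call. = FALSE)
  if (!inherits(map, "intensity_map")) stop("`map` must be an intensity_map", call. = FALSE)
  d3 <- dim(pair$adc_norm)
  v <- map$value(pair$adc_norm, pair$dwi_norm)
  out <- if (map$mode == "gray") array(v, dim = d3) else array(v, dim = c(d3, 3L))
  structure(out, params = map$params, mode = map$mode,
            class = c("mcdi_volume", "array"))
}

#' @export
print.mcdi_volume <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<mcdi_volume> shape %s, %s, map level %s (tilt %.1f, suppression %.3f, tau %.3f)\n",
              paste(dim(x), collapse = "x"), attr(x, "mode"),
              ifelse(is.na(p$level), "custom", p$level), p$tilt, p$suppression, p$tau))
  invisible(x)
}

#' Fuse at several suppression levels
#'
#' One mcDI per requested level, each identical to a direct [fuse()] call
#' with that level's map — the "sliding scale" of the reading workstation.
#'
#' @param pair a [normalized_pair()].
#' @param levels integer vector with entries in 1..9 (default all nine).
#' @param tau no-tumor-zone threshold passed to every map.
#' @param tilt_step,suppression_step schedule increments, see
#'   [intensity_map()].
#' @return Named list of `mcdi_volume`s (`"level_1"`, ...).
#' @export
fuse_series <- function(pair, levels = 1:9, tau = 0.05, tilt_step = 10,
                        suppression_step = 1 / 8) {
  if (length(levels) == 0L) stop("`levels` must be non-empty", call. = FALSE)
  if (any(is.na(levels)) || any(levels != as.integer(levels)) ||
      any(levels < 1) || any(levels > 9)) {
    stop("`levels` entries must be integers in 1..9", call. = FALSE)
  }
  out <- lapply(levels, function(l) {
    fuse(pair, intensity_map(level = l, tau = tau, tilt_step = tilt_step,
                             suppression_step = suppression_step))
  })
  names(out) <- paste0("level_", levels)
  out
}

#' Per-class intensity statistics of an mcDI
#'
#' Summarizes a (grayscale) image per tissue class and reports the
#' tumor-vs-peripheral-zone contrast `|mean(PCa) - mean(PZ)|` — the
#' quantity the fusion is meant to increase relative to the plain
#' normalized ADC.
#'
#' @param mcdi an `mcdi_volume` (gray mode) or any 3D array in \[0,1\].
#' @param mask a [label_mask()] with the image's shape.
#' @param labels legend entries to report (default: every legend entry).
#'   A requested label absent from the mask yields an `NA` row, not an
#'   error.
#' @return An `mcdi_contrast` object: a tibble with columns `class`,
#'   `label`, `n_voxels`, `mean`, `sd`, carrying the tumor-vs-PZ contrast
#'   as attribute `"contrast"` (also via [glance()]).
#' @export
contrast_report <- function(mcdi, mask, labels = NULL) {
  if (length(dim(mcdi)) == 4L) {
    stop("contrast_report expects a grayscale image", call. = FALSE)
  }
  stopifnot_same_shape(mcdi, mask, "image and mask")
  legend <- mask_legend(mask)
  if (is.null(labels)) labels <- names(legend)
  vals <- as.vector(unclass(mcdi))
  lab <- as.integer(mask)

  rows <- lapply(labels, function(l) {
    value <- resolve_label(mask, l)
    sel <- lab == value
    n <- sum(sel)
    tibble::tibble(
      class = names(legend)[match(value, legend)],
      label = value,
      n_voxels = n,
      mean = if (n > 0) mean(vals[sel]) else NA_real_,
      sd = if (n > 1) stats::sd(vals[sel]) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)

  contrast <- NA_real_
  if (all(c("pca", "pz") %in% names(legend))) {
    m <- function(value) {
      sel <- lab == value
      if (any(sel)) mean(vals[sel]) else NA_real_
    }
    contrast <- abs(m(legend[["pca"]]) - m(legend[["pz"]]))
  }
  structure(out, contrast = contrast,
            class = c("mcdi_contrast", class(out)))
}

#' @export
print.mcdi_contrast <- function(x, ...) {
  NextMethod()
  cat(sprintf("tumor-vs-PZ contrast: %s\n",
              format(attr(x, "contrast"), digits = 4)))
  invisible(x)
}

#' Tumor-vs-PZ contrast of a contrast report
#'
#' @param report an `mcdi_contrast` from [contrast_report()].
#' @return `|mean(PCa) - mean(PZ)|`, or `NA` if either class is absent.
#' @export
tumor_pz_contrast <- function(report) attr(report, "contrast")

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mcdi_contrast <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.mcdi_contrast <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x),
    n_voxels = sum(x$n_voxels),
    tumor_pz_contrast = attr(x, "contrast")
  )
}
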