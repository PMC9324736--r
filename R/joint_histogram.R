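# 2D DWI-ADC joint histograms.
#
# Each voxel of a tissue class is binned by its (adc_norm, dwi_norm)
# coordinate into a 256 x 256 count grid: bin k covers [k/256, (k+1)/256)
# with the last bin closed so 1.0 is representable. For display the counts
# are compressed to I = floor(ln(max(A, 1))) so that empty and single-count
# bins both render as 0 and each gray step represents an e-fold increase in
# voxel density.

HIST_BINS <- 256L

#' Accumulate a per-class 2D DWI-ADC histogram
#'
#' Bins every voxel of the selected tissue class by its normalized
#' (ADC, DWI) coordinate. Bin index is `floor(value * 256)` with 1.0
#' assigned to bin 255 (closed right edge). ADC indexes the first
#' dimension (x), DWI the second (y).
#'
#' @param pair a [normalized_pair()].
#' @param mask optional [label_mask()] with the pair's shape; `NULL`
#'   accumulates every voxel.
#' @param label legend entry (name such as `"pca"` or integer label) to
#'   select; ignored when `mask` is `NULL`.
#' @return A `histogram2d`: 256 x 256 integer count matrix with fields
#'   `n_total` and `class_label` as attributes.
#' @export
accumulate <- function(pair, mask = NULL, label = NULL) {
  if (!inherits(pair, "normalized_pair")) stop("`pair` must be a normalized_pair", call. = FALSE)
  a <- pair$adc_norm
  d <- pair$dwi_norm
  class_label <- NA_character_
  if (!is.null(mask)) {
    stopifnot_same_shape(pair$adc_norm, mask, "pair and mask")
    if (is.null(label)) stop("`label` is required when a mask is given", call. = FALSE)
    value <- resolve_label(mask, label)
    sel <- as.integer(mask) == value
    a <- a[sel]
    d <- d[sel]
    legend <- mask_legend(mask)
    class_label <- names(legend)[match(value, legend)]
  }
  ai <- pmin(floor(a * HIST_BINS), HIST_BINS - 1L)
  di <- pmin(floor(d * HIST_BINS), HIST_BINS - 1L)
  idx <- ai + HIST_BINS * di + 1L  # adc fastest -> counts[adc_bin+1, dwi_bin+1]
  counts <- matrix(tabulate(idx, nbins = HIST_BINS * HIST_BINS),
                   nrow = HIST_BINS, ncol = HIST_BINS)
  structure(counts, n_total = length(a), class_label = class_label,
            class = c("histogram2d", "matrix", "array"))
}

#' @export
print.histogram2d <- function(x, ...) {
  cat(sprintf("<histogram2d> %dx%d bins, %d voxels%s, %d bins occupied\n",
              nrow(x), ncol(x), attr(x, "n_total"),
              if (is.na(attr(x, "class_label"))) "" else
                sprintf(" (class %s)", attr(x, "class_label")),
              sum(unclass(x) > 0)))
  invisible(x)
}

#' Log-compress histogram counts for display
#'
#' I = floor(ln(A)) with A floored at 1, so counts 0 and 1 both map to
#' intensity 0 and each unit step is an e-fold density increase.
#'
#' @param hist a `histogram2d` (or any non-negative count matrix).
#' @return Integer matrix of the same shape, class `histogram_intensity`.
#' @export
log_intensity <- function(hist) {
  counts <- unclass(hist)
  attributes(counts) <- list(dim = dim(hist))
  intensity <- floor(log(pmax(counts, 1)))
  storage.mode(intensity) <- "integer"
  structure(intensity, class_label = attr(hist, "class_label"),
            class = c("histogram_intensity", "matrix", "array"))
}

#' Fuse per-class histograms into one RGB overlay
#'
#' Renders each class's log intensity into its conventional channel —
#' tumor (PCa) red, peripheral zone green, transitional zone blue,
#' background gray — scaled per channel by its own maximum level, and
#' overlays them additively (clipped to \[0,1\]).
#'
#' @param hists named list of `histogram2d` objects; recognized names are
#'   `pca`, `pz`, `tz`, `background` (missing classes are simply absent).
#' @return 256 x 256 x 3 RGB array in \[0,1\], indexed (adc_bin, dwi_bin,
#'   channel).
#' @export
composite_histogram <- function(hists) {
  if (!is.list(hists) || length(hists) == 0L || is.null(names(hists))) {
    stop("`hists` must be a named list of histograms", call. = FALSE)
  }
  dims <- unique(lapply(hists, dim))
  if (length(dims) != 1L) stop("histograms must share one binning", call. = FALSE)
  d <- dims[[1]]
  channels <- list(pca = 1L, pz = 2L, tz = 3L, background = 1:3)
  unknown <- setdiff(names(hists), names(channels))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown class name(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  rgb <- array(0, dim = c(d, 3L))
  for (nm in names(hists)) {
    lev <- unclass(log_intensity(hists[[nm]]))
    top <- max(lev)
    if (top == 0L) next
    scaled <- lev / top
    for (ch in channels[[nm]]) rgb[, , ch] <- rgb[, , ch] + scaled
  }
  rgb[rgb > 1] <- 1
  rgb
}
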