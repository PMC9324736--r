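# Mono-exponential diffusion math.
#
# The signal model is S(b) = S0 * exp(-b * ADC) with b in s/mm^2 and ADC in
# mm^2/s. ADC maps are kept on the 12-bit scanner storage scale: 1 stored
# unit = 1e-6 mm^2/s, ceiling 4095 (= 2^12 - 1), so a stored value of 1000
# is 1.0e-3 mm^2/s.

#' ADC storage-scale ceiling (12-bit)
#' @export
ADC_MAX <- 4095

ADC_STORAGE_PER_PHYS <- 1e6  # stored units per mm^2/s

#' Diffusion series: co-registered volumes at several b-values
#'
#' @param volumes list of [volume3d()] (or 3D arrays), one per b-value,
#'   all sharing one shape.
#' @param b_values strictly increasing diffusion weightings in s/mm^2, >= 0.
#' @return A `diffusion_series` object.
#' @export
diffusion_series <- function(volumes, b_values) {
  if (!is.list(volumes) || length(volumes) < 2L) {
    stop("need at least two b-value volumes", call. = FALSE)
  }
  b_values <- as.numeric(b_values)
  if (length(b_values) != length(volumes)) {
    stop("`volumes` and `b_values` lengths differ", call. = FALSE)
  }
  if (any(b_values < 0) || any(diff(b_values) <= 0)) {
    stop("`b_values` must be non-negative and strictly increasing", call. = FALSE)
  }
  volumes <- lapply(volumes, function(v) if (inherits(v, "volume3d")) v else volume3d(v))
  for (v in volumes[-1]) stopifnot_same_shape(volumes[[1]], v, "series volumes")
  structure(list(volumes = volumes, b_values = b_values), class = "diffusion_series")
}

#' @export
print.diffusion_series <- function(x, ...) {
  cat(sprintf("<diffusion_series> b = %s s/mm^2, shape %s\n",
              paste(x$b_values, collapse = ", "),
              paste(dim(x$volumes[[1]]), collapse = "x")))
  invisible(x)
}

series_volume <- function(series, b) {
  i <- match(b, series$b_values)
  if (is.na(i)) {
    stop(sprintf("b=%g s/mm^2 is not in the series (has: %s)", b,
                 paste(series$b_values, collapse = ", ")), call. = FALSE)
  }
  series$volumes[[i]]
}

#' ADC map on the 12-bit storage scale
#'
#' @param values 3D array of ADC in 1e-6 mm^2/s units, clipped to
#'   \[0, 4095\].
#' @return An `adc_volume` object.
#' @export
adc_volume <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("ADC values must be finite", call. = FALSE)
  }
  if (any(values < 0) || any(values > ADC_MAX)) {
    stop(sprintf("ADC values must lie in [0, %d] (storage scale)", ADC_MAX), call. = FALSE)
  }
  structure(unclass(values), class = c("adc_volume", "array"))
}

#' @export
print.adc_volume <- function(x, ...) {
  cat(sprintf("<adc_volume> shape %s, range [%g, %g] x 1e-6 mm^2/s\n",
              paste(dim(x), collapse = "x"), min(x), max(x)))
  invisible(x)
}

#' Fit the apparent diffusion coefficient from two b-values
#'
#' Mono-exponential two-point estimate
#' ADC = ln(S(b_low) / S(b_high)) / (b_high - b_low), reported on the 12-bit
#' storage scale (1e-6 mm^2/s) and clipped to \[0, 4095\]. Voxels with a
#' non-positive signal at either b-value get ADC 0 (background/air guard).
#'
#' @param series a [diffusion_series()].
#' @param b_low,b_high the two b-values to use; both must be in the series.
#' @return An [adc_volume()].
#' @export
fit_adc <- function(series, b_low = 0, b_high = 800) {
  if (!inherits(series, "diffusion_series")) stop("`series` must be a diffusion_series", call. = FALSE)
  if (b_low >= b_high) stop("`b_low` must be less than `b_high`", call. = FALSE)
  s_lo <- as_array3d(series_volume(series, b_low))
  s_hi <- as_array3d(series_volume(series, b_high))
  ok <- s_lo > 0 & s_hi > 0
  adc <- array(0, dim = dim(s_lo))
  adc[ok] <- log(s_lo[ok] / s_hi[ok]) / (b_high - b_low) * ADC_STORAGE_PER_PHYS
  adc[adc < 0] <- 0
  adc[adc > ADC_MAX] <- ADC_MAX
  adc_volume(adc)
}

#' Extrapolate a computed DWI (cDWI) to another b-value
#'
#' S(b_target) = S(b_ref) * exp(-ADC * (b_target - b_ref)), with ADC taken
#' from the storage scale (1 unit = 1e-6 mm^2/s). Extrapolating a b0/b800
#' acquisition to b = 1500 s/mm^2 yields the computed high-b-value image.
#'
#' @param series a [diffusion_series()] containing `b_ref`.
#' @param adc an [adc_volume()] with the series' shape.
#' @param b_ref reference b-value present in the series.
#' @param b_target target b-value, >= 0.
#' @return A [volume3d()] with the extrapolated signal.
#' @export
compute_cdwi <- function(series, adc, b_ref = 800, b_target = 1500) {
  if (!inherits(adc, "adc_volume")) stop("`adc` must be an adc_volume", call. = FALSE)
  if (b_target < 0) stop("`b_target` must be >= 0", call. = FALSE)
  s_ref <- series_volume(series, b_ref)
  stopifnot_same_shape(s_ref, adc, "signal and ADC volumes")
  phys <- unclass(adc) / ADC_STORAGE_PER_PHYS
  out <- as_array3d(s_ref) * exp(-phys * (b_target - b_ref))
  volume3d(out, spacing = attr(s_ref, "spacing"), affine = attr(s_ref, "affine"))
}

#' Normalize a DWI volume by the per-patient series maximum
#'
#' Divides `hb_volume` by the global maximum intensity across all b-value
#' volumes of the series (all b-values, all slices) — in vivo that maximum
#' is urine in the bladder at b = 0. Result lies in \[0, 1\].
#'
#' @param series the patient's full [diffusion_series()].
#' @param hb_volume the (computed or measured) high-b-value volume to
#'   normalize.
#' @param robust_quantile optional quantile in (0, 1\] used instead of the
#'   literal maximum (hot-pixel resilience); `NULL` (default) follows the
#'   literal global-maximum rule.
#' @return 3D array in \[0, 1\].
#' @export
normalize_dwi <- function(series, hb_volume, robust_quantile = NULL) {
  gmax <- if (is.null(robust_quantile)) {
    max(vapply(series$volumes, max, 0))
  } else {
    stopifnot(robust_quantile > 0, robust_quantile <= 1)
    as.numeric(stats::quantile(unlist(lapply(series$volumes, as_array3d)),
                               robust_quantile, names = FALSE))
  }
  if (gmax <= 0) stop("degenerate input: all-zero diffusion series", call. = FALSE)
  out <- as_array3d(hb_volume) / gmax
  out[out > 1] <- 1
  out
}

#' Normalize an ADC map by the 12-bit storage ceiling
#'
#' Divides by 4095, the potential maximum of the storage scale.
#'
#' @param adc an [adc_volume()].
#' @return 3D array in \[0, 1\].
#' @export
normalize_adc <- function(adc) {
  if (!inherits(adc, "adc_volume")) stop("`adc` must be an adc_volume", call. = FALSE)
  unclass(adc) / ADC_MAX
}

#' Per-voxel (ADC, DWI) coordinates on the unit square
#'
#' Bundles the two normalized grids that every histogram, intensity-map
#' lookup and fusion operates on.
#'
#' @param adc_norm 3D array in \[0,1\] (normalized ADC).
#' @param dwi_norm 3D array in \[0,1\] (normalized high-b DWI), same shape.
#' @return A `normalized_pair` object.
#' @export
normalized_pair <- function(adc_norm, dwi_norm) {
  if (!is.array(adc_norm) || !is.array(dwi_norm) ||
      length(dim(adc_norm)) != 3L || length(dim(dwi_norm)) != 3L) {
    stop("both grids must be 3D arrays", call. = FALSE)
  }
  stopifnot_same_shape(adc_norm, dwi_norm, "normalized grids")
  rng <- range(adc_norm, dwi_norm)
  if (anyNA(rng) || rng[1] < 0 || rng[2] > 1) {
    stop("normalized values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(adc_norm = unclass(adc_norm), dwi_norm = unclass(dwi_norm)),
            class = "normalized_pair")
}

#' @export
print.normalized_pair <- function(x, ...) {
  cat(sprintf("<normalized_pair> shape %s, adc [%0.3f, %0.3f], dwi [%0.3f, %0.3f]\n",
              paste(dim(x$adc_norm), collapse = "x"),
              min(x$adc_norm), max(x$adc_norm), min(x$dwi_norm), max(x$dwi_norm)))
  invisible(x)
}

#' @export
dim.normalized_pair <- function(x) dim(x$adc_norm)

#' Full normalization chain for one patient
#'
#' Fits the ADC (unless one is supplied), extrapolates the computed
#' high-b-value DWI, and normalizes both onto the unit square.
#'
#' @param series a [diffusion_series()].
#' @param adc optional externally supplied [adc_volume()]; fitted from
#'   `b_low`/`b_high` when `NULL`.
#' @param b_low,b_high b-values used for the ADC fit.
#' @param b_target b-value of the computed DWI (default 1500 s/mm^2).
#' @return A [normalized_pair()].
#' @export
normalize_patient <- function(series, adc = NULL, b_low = 0, b_high = 800,
                              b_target = 1500) {
  if (is.null(adc)) adc <- fit_adc(series, b_low, b_high)
  hb <- compute_cdwi(series, adc, b_ref = b_high, b_target = b_target)
  normalized_pair(normalize_adc(adc), normalize_dwi(series, hb))
}
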