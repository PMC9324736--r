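# Parameterized intensity maps on the unit (ADC, DWI) square.
#
# The map is a continuous analytic function value(a, d) -> [0,1], evaluated
# exactly at fusion time and only rasterized for display. Geometry:
#
#   * main gradient: black at ADC 0 to white at ADC 1 (ADC-like reading,
#     dark = suspicious);
#   * tilting the gradient axis clockwise by `tilt` degrees mixes in the
#     DWI channel: blend(a, d) = (cos t * a + sin t * (1 - d)) / (cos t +
#     sin t), rescaled so the reachable range is exactly [0, 1] per map;
#   * below the no-tumor zone (d < tau, default tau = 0.05 normalized DWI,
#     where in vivo essentially no tumor voxel lives) the value is pushed
#     toward white with weight suppression * (1 - d / tau), vanishing
#     continuously at d = tau.
#
# The nine selectable maps follow the schedule tilt(level) = (level-1) *
# 10 degrees and suppression(level) = (level-1)/8, so map 1 is exactly the
# original ADC image and map 9 the strongest DWI weighting / background
# suppression. The schedule constants are plain arguments, not magic
# numbers.

#' Construct an intensity map
#'
#' Builds one member of the map family, either by suppression `level`
#' (1–9, the slider of the reading workstation) or from explicit `tilt` /
#' `suppression` values.
#'
#' @param level integer 1–9; level 1 forces zero tilt and zero suppression
#'   (the identity/ADC map). May be `NULL` if `tilt` and `suppression` are
#'   both given.
#' @param tilt clockwise gradient tilt in degrees, in \[0, 90\]; defaults
#'   to `(level - 1) * tilt_step`.
#' @param suppression background push-to-white weight in \[0, 1\]; defaults
#'   to `(level - 1) * suppression_step`.
#' @param tau no-tumor-zone threshold on normalized DWI, in \[0, 1);
#'   default 0.05. `tau = 0` disables suppression.
#' @param tilt_step,suppression_step per-level schedule increments.
#' @param scheme `"grayscale"` or a registered color ramp (see
#'   [color_schemes()]).
#' @return An `intensity_map` with fields `params` (list) and `value`
#'   (vectorized function of `(a, d)`).
#' @export
intensity_map <- function(level = NULL, tilt = NULL, suppression = NULL,
                          tau = 0.05, tilt_step = 10, suppression_step = 1 / 8,
                          scheme = "grayscale") {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau >= 1) {
    stop("`tau` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(level)) {
    if (length(level) != 1L || is.na(level) || level != as.integer(level) ||
        level < 1 || level > 9) {
      stop("`level` must be an integer in 1..9", call. = FALSE)
    }
    level <- as.integer(level)
    if (level == 1L) {
      if ((!is.null(tilt) && tilt != 0) || (!is.null(suppression) && suppression != 0)) {
        stop("level 1 is the identity (ADC) map: tilt and suppression are fixed at 0",
             call. = FALSE)
      }
      tilt <- 0
      suppression <- 0
    } else {
      if (is.null(tilt)) tilt <- (level - 1) * tilt_step
      if (is.null(suppression)) suppression <- (level - 1) * suppression_step
    }
  } else {
    if (is.null(tilt) || is.null(suppression)) {
      stop("give either `level` or both `tilt` and `suppression`", call. = FALSE)
    }
    level <- NA_integer_
  }
  if (tilt < 0 || tilt > 90) stop("`tilt` must lie in [0, 90] degrees", call. = FALSE)
  if (suppression < 0 || suppression > 1) {
    stop("`suppression` must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(scheme, "grayscale") && !scheme %in% names(color_schemes())) {
    stop(sprintf("unknown color scheme '%s' (registered: %s)", scheme,
                 paste(c("grayscale", names(color_schemes())), collapse = ", ")),
         call. = FALSE)
  }

  params <- list(level = level, tilt = tilt, suppression = suppression, tau = tau,
                 tilt_step = tilt_step, suppression_step = suppression_step,
                 scheme = scheme)
  # cospi/sinpi are exact at multiples of 90 deg, keeping the level-1 (= a)
  # and pure-DWI (= 1 - d) limits identities rather than approximations
  ct <- cospi(tilt / 180)
  st <- sinpi(tilt / 180)
  # The tilted projection is rescaled to span [0,1] over the reachable
  # region. With suppression off that region is the whole unit square
  # (span cos+sin); with suppression on, the gradient's operative region is
  # d >= tau (the no-tumor zone below is overridden toward white), so the
  # span is cos + sin*(1-tau). This also makes the background value
  # non-decreasing in level at every fixed (a, d < tau): the sub-tau blend
  # satisfies blend >= a and grows with tilt there (c = 1-d > (1-tau)*a).
  w <- suppression
  span <- ct + st * (if (w > 0 && tau > 0) 1 - tau else 1)

  gray_value <- function(a, d) {
    a <- pmin(pmax(a, 0), 1)  # defensive clip; inputs are [0,1] by invariant
    d <- pmin(pmax(d, 0), 1)
    v <- (ct * a + st * (1 - d)) / span
    if (w > 0 && tau > 0) {
      s <- w * pmax(1 - d / tau, 0)
      v <- v + s * (1 - v)
    }
    pmin(pmax(v, 0), 1)
  }

  if (identical(scheme, "grayscale")) {
    value <- gray_value
    mode <- "gray"
  } else {
    ramp <- color_schemes()[[scheme]]
    value <- function(a, d) {
      a <- pmin(pmax(a, 0), 1)
      d <- pmin(pmax(d, 0), 1)
      blend <- pmin(pmax((ct * a + st * (1 - d)) / span, 0), 1)
      col <- ramp(blend)  # n x 3 in [0,1]
      bg <- d < tau
      if (any(bg)) {
        g <- 0.5 * a[bg]  # vertical grayscale gradient, capped at 50% gray
        col[bg, 1] <- g
        col[bg, 2] <- g
        col[bg, 3] <- g
      }
      col
    }
    mode <- "rgb"
  }

  structure(list(params = params, value = value, mode = mode),
            class = "intensity_map")
}

#' @rdname intensity_map
#' @param params an existing parameter list (as in `map$params`), used to
#'   rebuild a map, e.g. after reading a config file.
#' @export
build_map <- function(level = 5, tilt = NULL, suppression = NULL, tau = 0.05,
                      tilt_step = 10, suppression_step = 1 / 8) {
  intensity_map(level = level, tilt = tilt, suppression = suppression, tau = tau,
                tilt_step = tilt_step, suppression_step = suppression_step,
                scheme = "grayscale")
}

#' Registered color ramps for color-mode maps
#'
#' Each ramp maps the tilted blend coordinate t in \[0,1\] (0 = most
#' suspicious) to an RGB triple. `"grayscale"` is handled separately and
#' yields output identical to the gray map.
#'
#' @return Named list of vectorized ramp functions `t -> n x 3 matrix`.
#' @export
color_schemes <- function() {
  make <- function(colors) {
    cr <- grDevices::colorRamp(colors, space = "rgb")
    function(t) cr(pmin(pmax(t, 0), 1)) / 255
  }
  list(
    hot  = make(c("#B80000", "#FF6A00", "#FFD300", "#FFFFFF")),
    cool = make(c("#001E96", "#0092D2", "#7BE0FF", "#FFFFFF")),
    pet  = make(c("#000000", "#B80000", "#FFD300", "#FFFFFF"))
  )
}

#' Build a color-mode intensity map
#'
#' Color variant of [build_map()]: above the no-tumor zone the tilted blend
#' coordinate indexes a color ramp; below it a vertical grayscale gradient
#' in ADC is shown whose brightest value is 50% gray (not white), keeping
#' the background dark. With `scheme = "grayscale"` the output is identical
#' to [build_map()] everywhere.
#'
#' @inheritParams intensity_map
#' @param scheme ramp name: `"grayscale"` or one of [color_schemes()].
#' @return An `intensity_map` in RGB mode (gray mode for `"grayscale"`).
#' @export
build_color_map <- function(level = 5, scheme = "hot", tilt = NULL,
                            suppression = NULL, tau = 0.05, tilt_step = 10,
                            suppression_step = 1 / 8) {
  intensity_map(level = level, tilt = tilt, suppression = suppression, tau = tau,
                tilt_step = tilt_step, suppression_step = suppression_step,
                scheme = scheme)
}

#' @export
print.intensity_map <- function(x, ...) {
  p <- x$params
  cat(sprintf("<intensity_map> level %s: tilt %.1f deg, suppression %.3f, tau %.3f, scheme %s\n",
              ifelse(is.na(p$level), "custom", p$level), p$tilt, p$suppression,
              p$tau, p$scheme))
  invisible(x)
}

#' Evaluate an intensity map
#'
#' @param map an [intensity_map()].
#' @param a,d normalized ADC / DWI coordinates (vectors or arrays of equal
#'   shape).
#' @return Gray values with the shape of `a` (gray mode) or an `n x 3` RGB
#'   matrix (color mode).
#' @export
map_value <- function(map, a, d) {
  v <- map$value(a, d)
  if (map$mode == "gray" && !is.null(dim(a))) dim(v) <- dim(a)
  v
}

#' Rasterize an intensity map
#'
#' Samples the map at bin centers: `raster[i, j] = value((i - 0.5) / res,
#' (j - 0.5) / res)` with the first index running over ADC and the second
#' over DWI.
#'
#' @param map an [intensity_map()].
#' @param resolution grid size per axis, >= 2 (default 256).
#' @return `resolution x resolution` gray matrix, or
#'   `resolution x resolution x 3` RGB array in color mode.
#' @export
rasterize <- function(map, resolution = 256L) {
  if (length(resolution) != 1L || is.na(resolution) || resolution < 2) {
    stop("`resolution` must be an integer >= 2", call. = FALSE)
  }
  resolution <- as.integer(resolution)
  centers <- (seq_len(resolution) - 0.5) / resolution
  a <- matrix(centers, resolution, resolution)          # varies along rows (ADC)
  d <- matrix(centers, resolution, resolution, byrow = TRUE)  # along cols (DWI)
  v <- map$value(a, d)
  if (map$mode == "gray") {
    matrix(v, resolution, resolution)
  } else {
    array(v, dim = c(resolution, resolution, 3L))
  }
}

#' Serialize map parameters to a plain-text (JSON) config
#'
#' @param map an [intensity_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_config <- function(map, path) {
  p <- map$params
  p$level <- if (is.na(p$level)) NULL else p$level
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Rebuild an intensity map from a JSON config
#'
#' @param path config written by [write_map_config()].
#' @return An [intensity_map()].
#' @export
read_map_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  intensity_map(level = p$level, tilt = p$tilt, suppression = p$suppression,
                tau = p$tau, tilt_step = p$tilt_step %||% 10,
                suppression_step = p$suppression_step %||% (1 / 8),
                scheme = p$scheme %||% "grayscale")
}
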