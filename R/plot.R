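# ggplot2 displays. Histogram/map rasters are indexed (adc, dwi); plots put
# normalized ADC on x and normalized DWI on y, as the joint histograms are
# conventionally drawn.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_to_tibble <- function(m, value_name = "value") {
  res_a <- nrow(m)
  res_d <- ncol(m)
  tibble::tibble(
    adc = rep((seq_len(res_a) - 0.5) / res_a, times = res_d),
    dwi = rep((seq_len(res_d) - 0.5) / res_d, each = res_a),
    !!value_name := as.vector(m)
  )
}

rgb_raster_to_tibble <- function(arr) {
  df <- raster_to_tibble(arr[, , 1], "r")
  df$g <- as.vector(arr[, , 2])
  df$b <- as.vector(arr[, , 3])
  df$rgb <- grDevices::rgb(df$r, df$g, df$b)
  df
}

#' Plot an intensity map
#'
#' @param object an [intensity_map()].
#' @param resolution raster resolution (default 256).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.intensity_map <- function(object, resolution = 256L, ...) {
  ras <- rasterize(object, resolution)
  p <- object$params
  ttl <- sprintf("Intensity map (level %s, tilt %g°, suppression %.2f, τ %.2f)",
                 ifelse(is.na(p$level), "custom", p$level), p$tilt, p$suppression, p$tau)
  if (object$mode == "gray") {
    df <- raster_to_tibble(ras)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$adc, y = .data$dwi, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1),
                                   name = "gray") +
      ggplot2::coord_fixed(expand = FALSE) +
      ggplot2::labs(x = "normalized ADC", y = "normalized DWI", title = ttl) +
      ggplot2::theme_minimal()
  } else {
    df <- rgb_raster_to_tibble(ras)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$adc, y = .data$dwi, fill = .data$rgb)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_identity() +
      ggplot2::coord_fixed(expand = FALSE) +
      ggplot2::labs(x = "normalized ADC", y = "normalized DWI", title = ttl) +
      ggplot2::theme_minimal()
  }
}

#' Plot a 2D DWI-ADC histogram (log-intensity display)
#'
#' @param object a `histogram2d` or `histogram_intensity`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.histogram2d <- function(object, ...) {
  lev <- unclass(log_intensity(object))
  df <- raster_to_tibble(lev, "intensity")
  cl <- attr(object, "class_label")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adc, y = .data$dwi, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black", name = "I = int(ln A)") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "normalized ADC", y = "normalized DWI",
                  title = if (is.na(cl)) "2D DWI-ADC histogram"
                          else sprintf("2D DWI-ADC histogram (%s)", cl)) +
    ggplot2::theme_minimal()
}

#' Plot one slice of an mcDI volume
#'
#' @param object an `mcdi_volume`.
#' @param slice slice index (default: middle slice).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mcdi_volume <- function(object, slice = NULL, ...) {
  d <- dim(object)
  if (is.null(slice)) slice <- ceiling(d[1] / 2)
  if (attr(object, "mode") == "gray") {
    img <- unclass(object)[slice, , ]
    df <- tibble::tibble(
      col = rep(seq_len(d[3]), each = d[2]),
      row = rep(seq_len(d[2]), times = d[3]),
      value = as.vector(img)
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1),
                                   name = "gray") +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed(expand = FALSE) +
      ggplot2::labs(x = NULL, y = NULL, title = sprintf("mcDI, slice %d", slice)) +
      ggplot2::theme_void() +
      ggplot2::theme(plot.title = ggplot2::element_text())
  } else {
    img <- unclass(object)[slice, , , , drop = TRUE]
    df <- tibble::tibble(
      col = rep(seq_len(d[3]), each = d[2]),
      row = rep(seq_len(d[2]), times = d[3]),
      rgb = grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                           as.vector(img[, , 3]))
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$rgb)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_identity() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed(expand = FALSE) +
      ggplot2::labs(x = NULL, y = NULL, title = sprintf("mcDI, slice %d", slice)) +
      ggplot2::theme_void() +
      ggplot2::theme(plot.title = ggplot2::element_text())
  }
}

#' @importFrom rlang .data :=
NULL
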