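# ggplot2 visualizations of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_tile
#'   geom_histogram scale_fill_gradient2 scale_color_manual facet_wrap labs
#'   coord_fixed theme_minimal
#' @export
ggplot2::autoplot

# azimuthal-equidistant projection of unit-sphere electrode positions
project_sensors <- function(channels) {
  theta <- acos(pmin(1, pmax(-1, channels$z)))
  phi <- atan2(channels$y, channels$x)
  tibble(
    channel = channels$channel,
    px = theta * cos(phi), py = theta * sin(phi)
  )
}

#' Plot a time-frequency representation
#'
#' Power raster (time x frequency) averaged over channels, or for one
#' channel.
#'
#' @param object An `eeg_tfr`.
#' @param channel Optional channel label; default averages all channels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_tfr <- function(object, channel = NULL, ...) {
  p <- if (is.null(channel)) {
    apply(object$power, c(2, 3), mean)
  } else {
    object$power[match(channel, object$channels$channel), , ]
  }
  df <- tibble(
    freq = rep(object$freqs, each = length(object$times)),
    time = rep(object$times, length(object$freqs)),
    power = as.vector(t(p))
  )
  ggplot(df, aes(.data$time, .data$freq, fill = .data$power)) +
    geom_raster() +
    labs(
      x = "time (s)", y = "frequency (Hz)", fill = "power",
      title = sprintf("TFR: %s / %s", object$subject, object$condition)
    ) +
    theme_minimal()
}

#' Plot a sensor topography of a statistic
#'
#' Projected electrode positions colored by a per-channel value, with an
#' optional highlighted channel set (e.g. a significant cluster).
#'
#' @param array A [make_sensor_array()] tibble.
#' @param values Named numeric vector (channel -> value) or a `band_power`
#'   tibble.
#' @param highlight Channel labels to outline.
#' @return A ggplot object.
#' @export
plot_topography <- function(array, values, highlight = NULL) {
  proj <- project_sensors(array)
  if (is.data.frame(values)) {
    values <- stats::setNames(values$power, values$channel)
  }
  proj$value <- unname(values[proj$channel])
  proj$highlight <- proj$channel %in% (highlight %||% character(0))
  ggplot(proj, aes(.data$px, .data$py)) +
    geom_point(aes(color = .data$value), size = 4) +
    geom_point(
      data = proj[proj$highlight, ], shape = 21, size = 6, stroke = 1.2,
      color = "black", fill = NA
    ) +
    ggplot2::scale_color_gradient2(low = "navy", mid = "white", high = "firebrick") +
    coord_fixed() +
    labs(x = NULL, y = NULL, color = "value") +
    theme_minimal()
}

#' Plot a source contrast map as axial slices
#'
#' @param object A `source_contrast_map` (or `source_power_map` with
#'   `value`).
#' @param value Name of the value column (default `"contrast"`).
#' @param ... Unused.
#' @return A ggplot object of tiled axial slices.
#' @export
autoplot.source_contrast_map <- function(object, value = "contrast", ...) {
  df <- as_tibble(object)
  df$value <- df[[value]]
  ggplot(df, aes(.data$x, .data$y, fill = .data$value)) +
    geom_tile() +
    facet_wrap(~z) +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    coord_fixed() +
    labs(x = "x (mm)", y = "y (mm)", fill = value) +
    theme_minimal()
}

#' Plot the distribution of leave-one-out cluster statistics
#'
#' Histograms of a per-iteration statistic, faceted if records from several
#' groups are bound together (requires a `group` column).
#'
#' @param object A `loo_table` (optionally with a `group` column).
#' @param statistic Column to plot (default `"relative_t_sum"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loo_table <- function(object, statistic = "relative_t_sum", ...) {
  df <- as_tibble(object)
  df$value <- df[[statistic]]
  p <- ggplot(df[!is.na(df$value), ], aes(.data$value)) +
    geom_histogram(bins = 15, fill = "grey40") +
    labs(x = statistic, y = "iterations") +
    theme_minimal()
  if ("group" %in% names(df)) p <- p + facet_wrap(~group)
  p
}
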