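#' Plot a feature map
#'
#' Tile plot of a preferred parameter across the sheet (the classic
#' orientation-map view for `p1`).
#'
#' @param object A `cortex_map`.
#' @param parameter Which parameter column to show (default `"p1"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cortex_map <- function(object, parameter = "p1", ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$x_um, .data$y_um,
                               fill = .data[[parameter]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = parameter,
                  title = sprintf("%s map (%d x %d cells)",
                                  attr(object, "mode"),
                                  attr(object, "grid_side"),
                                  attr(object, "grid_side")))
}

#' Plot a similarity curve
#'
#' @param object A `similarity_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.similarity_curve <- function(object, ...) {
  xcol <- if ("delta_deg" %in% names(object)) "delta_deg" else "amplitude"
  ycol <- if ("mean_r" %in% names(object)) "mean_r" else "r"
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data[[xcol]], .data[[ycol]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(min(0, min(object[[ycol]], na.rm = TRUE)), 1) +
    ggplot2::labs(
      x = if (xcol == "delta_deg") "orientation difference (deg)"
          else "relative noise amplitude",
      y = "Pearson similarity"
    )
  if ("sd_r" %in% names(object)) {
    p <- p + ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                   ymax = .data$mean_r + .data$sd_r))
  }
  p
}

#' Spike-rate map of a trial
#'
#' @param trial A `trial_result`.
#' @param map The `cortex_map` the trial ran on.
#' @return A ggplot of per-cell spike counts at their sheet positions.
#' @export
plot_spike_map <- function(trial, map) {
  df <- dplyr::left_join(tibble::as_tibble(map), trial$counts, by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$spikes)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "spikes")
}
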