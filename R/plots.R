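#' Plot a height map
#'
#' Raster rendering of the topography with physical axes in micrometres,
#' using the viridis palette AFM figures typically use.
#'
#' @param object A [heightmap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot heightmap
#' @export
autoplot.heightmap <- function(object, ...) {
  df <- as_tibble.heightmap(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm / 1000, .data$y_nm / 1000,
                                   fill = .data$height_nm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a spatial roughness spectrum
#'
#' Spectral intensity versus spatial frequency with the two analysis windows
#' shaded (first order 600-1200 nm, second order 50-300 nm).
#'
#' @param object A `spatial_spectrum` from [profile_spectrum()].
#' @param log_y Use a log10 intensity axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spatial_spectrum
#' @export
autoplot.spatial_spectrum <- function(object, log_y = FALSE, ...) {
  wins <- dplyr::bind_rows(
    tibble::tibble(window = "order_I", lo = 1 / 1200, hi = 1 / 600),
    tibble::tibble(window = "order_II", lo = 1 / 300, hi = 1 / 50))
  p <- ggplot2::ggplot(object) +
    ggplot2::geom_rect(data = wins,
                       ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$window),
                       alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line(ggplot2::aes(.data$nu_per_nm, .data$S_nm2),
                       colour = "firebrick") +
    ggplot2::labs(x = expression(nu ~ (nm^-1)), y = expression(S ~ (nm^2))) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a cell-type distribution
#'
#' Stacked percentage bars per time point, one facet per activator: the
#' standard view of the type 1 to type 4 progression during activation.
#'
#' @param types A tibble from [type_distribution()] rows bound over time
#'   points (columns `activator`, `time_min`, `type_label`, `fraction_pct`).
#' @return A ggplot object.
#' @export
plot_type_distribution <- function(types) {
  ggplot2::ggplot(types,
                  ggplot2::aes(factor(.data$time_min), .data$fraction_pct,
                               fill = .data$type_label)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$activator)) +
    ggplot2::labs(x = "time (min)", y = "cells (%)", fill = "type") +
    ggplot2::theme_minimal()
}

#' Plot a particle size histogram
#'
#' @param hist_tbl A tibble from [size_histogram()].
#' @return A ggplot object of relative frequencies versus size.
#' @export
plot_size_histogram <- function(hist_tbl) {
  ggplot2::ggplot(hist_tbl,
                  ggplot2::aes(.data$bin_left_nm + diff(c(.data$bin_left_nm[1],
                                                          .data$bin_right_nm[1])) / 2,
                               .data$frequency)) +
    ggplot2::geom_col(width = hist_tbl$bin_right_nm[1] - hist_tbl$bin_left_nm[1],
                      fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = "size (nm)", y = "relative frequency") +
    ggplot2::theme_minimal()
}
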