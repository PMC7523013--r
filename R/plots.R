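#' Plot a diel cycle
#'
#' Hourly median line, interquartile ribbon, 10th-90th percentile whisker
#' ribbon and the campaign hourly mean as markers -- the conventional diel
#' box-plot summary of a VOC or meteorological series.
#'
#' @param object An `olf_diel` tibble from [diel_cycle()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot olf_diel
#' @export
autoplot.olf_diel <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$hour)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p10, ymax = .data$p90),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey65") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), shape = 21, fill = "white") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Local hour", y = "Mixing ratio (ppbv)") +
    ggplot2::theme_minimal()
}

#' Plot a bivariate polar map
#'
#' Mean mixing ratio as a function of wind direction (angle, meteorological
#' coming-from convention, north up) and wind speed (radius). Masked cells
#' are omitted.
#'
#' @param object An `olf_polar` tibble from [polar_bin()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot olf_polar
#' @export
autoplot.olf_polar <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$mean_vmr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wd_mid, y = .data$ws_mid,
                                   fill = .data$mean_vmr)) +
    ggplot2::geom_tile() +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 360), breaks = seq(0, 315, 45),
                                labels = c("N", "NE", "E", "SE", "S", "SW", "W", "NW")) +
    ggplot2::scale_fill_viridis_c(name = "ppbv") +
    ggplot2::labs(x = NULL, y = "Wind speed (m/s)") +
    ggplot2::theme_minimal()
}

#' Plot a wind profile occupancy rose
#'
#' Time-fraction per direction sector and speed class, compass convention
#' (sector centres shown at their coming-from direction).
#'
#' @param object An `olf_wind_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot olf_wind_profile
#' @export
autoplot.olf_wind_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$compass_deg, y = .data$fraction,
                               fill = factor(.data$speed_class))) +
    ggplot2::geom_col(width = 20) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 360), breaks = seq(0, 315, 45),
                                labels = c("N", "NE", "E", "SE", "S", "SW", "W", "NW")) +
    ggplot2::scale_fill_viridis_d(name = "Speed class") +
    ggplot2::labs(x = NULL, y = "Fraction of time") +
    ggplot2::theme_minimal()
}

#' Plot flight tracks with release and home sites
#'
#' @param tracks Fix table (`bird_id`, `lat`, `lon`).
#' @param sites Optional site table (`release_lat`, `release_lon`,
#'   `home_lat`, `home_lon`).
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, sites = NULL) {
  p <- ggplot2::ggplot(tracks, ggplot2::aes(x = .data$lon, y = .data$lat,
                                            group = .data$bird_id)) +
    ggplot2::geom_path(alpha = 0.5, colour = "steelblue") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
  if (!is.null(sites)) {
    p <- p +
      ggplot2::geom_point(data = sites,
                          ggplot2::aes(x = .data$release_lon, y = .data$release_lat),
                          inherit.aes = FALSE, shape = 17, size = 2) +
      ggplot2::geom_point(data = sites,
                          ggplot2::aes(x = .data$home_lon, y = .data$home_lat),
                          inherit.aes = FALSE, shape = 15, size = 2,
                          colour = "firebrick")
  }
  p
}
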