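#' Plot gap area over time
#'
#' @param object a [morphometrics_series()].
#' @param kinetics optional `closure_kinetics` fit to overlay.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.morphometrics_series <- function(object, kinetics = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$t_h, y = .data$area_um2)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time after wounding (h)",
                  y = expression("gap area (" * mu * m^2 * ")"))
  if (!is.null(kinetics)) {
    w <- kinetics$fit_window
    seg <- tibble(t_h = c(w[1], w[2]))
    seg$area_um2 <- predict(kinetics$fit, newdata = seg)
    p <- p + ggplot2::geom_line(data = seg, colour = "firebrick",
                                linewidth = 0.8)
  }
  p
}

#' Polar windrose plot of migration directionality
#'
#' Half-rose over [0, 180] degrees: 0 = toward the gap centroid,
#' 90 = tangential to the wound edge.
#'
#' @param rose tibble from [windrose()].
#' @return A ggplot.
#' @export
plot_windrose <- function(rose) {
  ggplot2::ggplot(rose, ggplot2::aes(x = .data$bin_mid_deg,
                                     y = .data$percent)) +
    ggplot2::geom_col(width = rose$bin_end_deg[1] - rose$bin_start_deg[1],
                      fill = "steelblue", colour = "grey20",
                      linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 180, 30)) +
    ggplot2::labs(x = "radial migration angle (deg)",
                  y = "frequency (%)")
}

#' Plot a tension time course
#'
#' @param object a `tension_series` from [total_tension()].
#' @param ... unused.
#' @return A ggplot; the dashed line is the pre-wound baseline tension.
#' @export
autoplot.tension_series <- function(object, ...) {
  base <- attr(object, "baseline_tension_uN")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$t_h, y = .data$tension_uN)) +
    ggplot2::geom_point(size = 1) + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time after wounding (h)",
                  y = expression("tissue tension (" * mu * N * ")"))
  if (!is.null(base) && !is.na(base))
    p <- p + ggplot2::geom_hline(yintercept = base, linetype = "dashed")
  p
}

#' Plot nuclear trajectories coloured by location class
#'
#' @param tracks tibble from [link_tracks()] or ground-truth tracks.
#' @param stats optional [migration_stats()] table supplying classes.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, stats = NULL) {
  if (!is.null(stats) && "track_id" %in% names(tracks))
    tracks <- left_join(tracks, stats[, c("track_id", "class")],
                        by = "track_id")
  aes <- if ("class" %in% names(tracks))
    ggplot2::aes(x = .data$x_um, y = .data$y_um, group = .data$track_id,
                 colour = .data$class)
  else ggplot2::aes(x = .data$x_um, y = .data$y_um, group = .data$track_id)
  ggplot2::ggplot(tracks, aes) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m)))
}
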