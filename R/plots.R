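#' Effect-versus-quantile curves
#'
#' Plots the estimated treatment-minus-control distance shift against the
#' quantile level for each treatment (and species, when present), with the
#' 95% cluster-bootstrap interval as a ribbon. Positive values mean bats
#' flew farther from the deterrent during the emission.
#'
#' @param object A `ud_qte` tibble from [quantile_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ud_qte <- function(object, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$tau, y = .data$estimate,
                                    color = .data$treatment,
                                    fill = .data$treatment)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "quantile (tau)",
                  y = "distance shift, treatment - control (m)",
                  color = "treatment", fill = "treatment")
  if ("species_code" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~species_code)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fused distance track
#'
#' Distance from the deterrent over the trial, with emission periods shaded.
#'
#' @param track Fused-track tibble with `frame`, `distance_m`,
#'   `period_label`.
#' @param schedule Optional [make_schedule()] for period shading (taken from
#'   the track attribute when present).
#' @param fps Frames per second for the time axis.
#' @return A ggplot object.
#' @export
plot_track <- function(track, schedule = attr(track, "schedule"), fps = 30) {
  if (!is.null(schedule)) fps <- attr(schedule, "fps") %||% fps
  p <- ggplot2::ggplot(track,
                       ggplot2::aes(x = .data$frame / fps / 60,
                                    y = .data$distance_m))
  if (!is.null(schedule)) {
    shade <- filter(schedule, .data$label %in% treatment_levels)
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_frame / fps / 60,
                   xmax = .data$end_frame / fps / 60,
                   ymin = -Inf, ymax = Inf, fill = .data$label),
      alpha = 0.15)
  }
  p + ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "trial time (min)", y = "distance from deterrent (m)",
                  fill = "emission")
}

#' Plot a simulated trajectory in the cage
#'
#' Top view (cage axis versus width) of a flight path, colored by period.
#'
#' @param traj A [simulate_flight()] trajectory.
#' @param cage A [cage_geometry()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, cage = cage_geometry()) {
  ggplot2::ggplot(traj, ggplot2::aes(.data$x_m, .data$y_m,
                                     color = .data$period_label)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.2) +
    ggplot2::coord_fixed(xlim = c(0, cage$length_m),
                         ylim = c(0, cage$width_m)) +
    ggplot2::labs(x = "cage axis (m)", y = "cage width (m)",
                  color = "period")
}
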