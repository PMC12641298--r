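#' Plot an Euler trajectory
#'
#' Line plot of the three Euler channels over time, faceted per angle.
#'
#' @param traj an `euler_trajectory`, or a named list of them (e.g.
#'   `list(sensor = ..., reference = ...)`) overlaid by colour.
#' @return a ggplot object.
#' @export
plot_euler_trajectory <- function(traj) {
  if (inherits(traj, "euler_trajectory")) traj <- list(series = traj)
  d <- purrr::imap_dfr(traj, function(tr, nm) {
    dplyr::mutate(
      tidyr::pivot_longer(as_tibble(tr), c("roll_deg", "pitch_deg", "yaw_deg"),
                          names_to = "angle", values_to = "deg"),
      series = nm)
  })
  d$angle <- factor(d$angle, levels = c("roll_deg", "pitch_deg", "yaw_deg"),
                    labels = c("roll (deg)", "pitch (deg)", "yaw (deg)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$deg, colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$angle), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.euler_trajectory <- function(object, ...) plot_euler_trajectory(object)

#' @export
autoplot.marg_pipeline <- function(object, ...) {
  plot_euler_trajectory(list(sensor = object$sensor, reference = object$reference)) +
    ggplot2::labs(title = sprintf("placement %s: aligned sensor vs reference",
                                  object$placement))
}

#' Plot a MARG recording's raw component streams
#'
#' @param object a `marg_recording`.
#' @param ... unused.
#' @return a ggplot object, components faceted by row.
#' @export
autoplot.marg_recording <- function(object, ...) {
  units <- c(accel = "accel (g)", gyro = "gyro (deg/s)", mag = "mag (gauss)")
  d <- purrr::imap_dfr(object[c("accel", "gyro", "mag")], function(comp, nm) {
    dplyr::mutate(tidyr::pivot_longer(comp, c("x", "y", "z"),
                                      names_to = "axis", values_to = "value"),
                  component = units[[nm]])
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$value, colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("placement %s (%s-handed)", object$placement,
                                  object$handedness)) +
    ggplot2::theme_minimal()
}

#' Plot a validation report as a category grid
#'
#' Tile grid of placements against movement x angle cells, filled by accuracy
#' category and labelled with the mean RMSE.
#'
#' @param report a `validation_report` from [summarize_validation()].
#' @return a ggplot object.
#' @export
plot_validation <- function(report) {
  d <- dplyr::mutate(report, col = paste(.data$movement, .data$angle, sep = "\n"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$placement,
                                  fill = .data$category)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$rmse_mean)),
                       size = 3) +
    ggplot2::scale_fill_manual(values = c(excellent = "#4daf4a", good = "#cccc66",
                                          unacceptable = "#e41a1c",
                                          missing = "grey80")) +
    ggplot2::labs(x = NULL, y = "placement", fill = "category",
                  title = "mean RMSE (deg) by placement and movement") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
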