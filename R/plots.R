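#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Node paths over time, one colour per cell.
#'
#' @param object A `trajectory_record`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory_record <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                    group = interaction(.data$cell_id,
                                                        .data$node_id),
                                    colour = factor(.data$cell_id))) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "cell") +
    ggplot2::theme_minimal()
}

#' Plot a force-velocity fit
#'
#' Data points with the fitted exponential decay curve.
#'
#' @param object An `fv_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fv_fit <- function(object, ...) {
  grid <- tibble::tibble(force = seq(min(object$data$force),
                                     max(object$data$force),
                                     length.out = 100))
  grid$velocity <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$force,
                                            y = .data$velocity)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "opposing force (pN)", y = "velocity (nm/s)") +
    ggplot2::theme_minimal()
}

#' Plot a bead trace with clamp windows
#'
#' @param object A `bead_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bead_trace <- function(object, ...) {
  ev <- attr(object, "events")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$pos_nm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "bead position (nm)") +
    ggplot2::theme_minimal()
  if (nrow(ev)) {
    p <- p + ggplot2::geom_rect(
      data = ev, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      fill = "orange", alpha = 0.2)
  }
  p
}

#' Plot a bond-stiffness sweep
#'
#' Maximum primary-cell orientation change versus substrate bond stiffness,
#' with the experimental comparison band.
#'
#' @param sweep Result of [sweep_kappa()].
#' @param band_mean,band_sd Experimental band, degrees.
#' @return A ggplot.
#' @export
plot_sweep_kappa <- function(sweep, band_mean = 15, band_sd = 15) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$kappa,
                                      y = .data$delta_theta_max)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band_mean - band_sd, ymax = band_mean + band_sd,
                      fill = "grey80", alpha = 0.5) +
    ggplot2::geom_hline(yintercept = band_mean, linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "bond stiffness κ (pN/µm)",
                  y = "max orientation change (deg)") +
    ggplot2::theme_minimal()
}

#' Plot an angle or position sweep for both coupling modes
#'
#' @param sweep Result of [sweep_angle()] or [sweep_position()].
#' @return A ggplot.
#' @export
plot_sweep_modes <- function(sweep) {
  xvar <- if ("angle" %in% names(sweep)) "angle" else "collision_node"
  yvar <- if ("delta_theta_max" %in% names(sweep)) "delta_theta_max" else
    "delta_theta_primary"
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]],
                                      colour = .data$mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = if (xvar == "angle") "collision angle (deg)" else
                    "collision node", y = "orientation change (deg)") +
    ggplot2::theme_minimal()
}
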