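#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a force-distance calibration
#'
#' Simulated drag-force samples (points) with the fitted logistic (line),
#' on the scale a calibration is usually read at: distance in micrometres,
#' force in piconewtons.
#'
#' @param object A `force_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot force_calibration
#' @export
autoplot.force_calibration <- function(object, ...) {
  grid <- tibble::tibble(x = seq(min(object$samples$x), max(object$samples$x),
                                 length.out = 200))
  grid$F <- applied_force(grid$x, object)
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$x * 1e6,
                                               y = .data$F * 1e12)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "distance from bottom wall (µm)",
      y = "applied drag force (pN)",
      title = sprintf("Force calibration, %g µl/min (r² = %.3f)",
                      object$flow_rate, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a creep-compliance fit
#'
#' Measured compliance (points) and the fitted four-element model (line)
#' over the creep window.
#'
#' @param object A `kv4_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kv4_fit
#' @export
autoplot.kv4_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$J), alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(
      x = "time since flow onset (s)", y = "creep compliance J(t) (1/Pa)",
      title = sprintf("E0+E1 = %.0f Pa, τ = %.2f s", object$E0_plus_E1,
                      object$tau)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a rupture survival curve
#'
#' Survival fraction against the applied step force; the detected rupture
#' step is highlighted.
#'
#' @param object A `rupture_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rupture_result
#' @export
autoplot.rupture_result <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !is.na(.data$force))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$force * 1e12,
                                        y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "applied force (pN)", y = "survival fraction",
                  title = "Bead attachment under the flow ramp") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!object$flagged) {
    p <- p + ggplot2::geom_vline(xintercept = object$rupture_force * 1e12,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot track displacements along the flow axis
#'
#' Projects every track on the flow axis from its first sample and overlays
#' the displacement series -- the raw observable of every measurement mode.
#'
#' @param table A `track_table`.
#' @param t0 Reference time, s (defaults to each track's first sample).
#' @return A ggplot.
#' @export
plot_displacement <- function(table, t0 = NULL) {
  fa <- flow_axis(table)
  series <- table |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(g, key) {
      out <- project_displacement(g, t0 = t0, flow_axis = fa)
      out$track_id <- key$track_id
      out
    }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time, y = .data$s,
                                       group = .data$track_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (s)", y = "displacement along flow (µm)") +
    ggplot2::theme_minimal()
}
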