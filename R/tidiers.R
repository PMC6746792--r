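#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a force calibration
#'
#' @param x A `force_calibration`.
#' @param ... Unused.
#' @return One row per logistic parameter: `term`, `estimate`, `unit`.
#' @method tidy force_calibration
#' @export
tidy.force_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("A1", "A2", "x0", "p"),
    estimate = c(x$A1, x$A2, x$x0, x$p),
    unit = c("N", "N", "m", "")
  )
}

#' @rdname tidy.force_calibration
#' @return `glance()`: one-row fit summary.
#' @method glance force_calibration
#' @export
glance.force_calibration <- function(x, ...) {
  tibble::tibble(
    flow_rate = x$flow_rate,
    r_squared = x$r_squared,
    n_heights = nrow(x$samples),
    F_at_h = applied_force(x$ctx$h, x)
  )
}

#' Tidy a four-element creep fit
#'
#' @param x A `kv4_fit`.
#' @param ... Unused.
#' @return One row per parameter (shear and converted Young's forms).
#' @method tidy kv4_fit
#' @export
tidy.kv4_fit <- function(x, ...) {
  tibble::tibble(
    term = c("G0", "G1", "mu0p", "mu1p", "tau", "E0", "E1", "mu0", "mu1",
             "E0_plus_E1"),
    estimate = c(x$G0, x$G1, x$mu0p, x$mu1p, x$tau, x$E0, x$E1, x$mu0,
                 x$mu1, x$E0_plus_E1),
    unit = c("Pa", "Pa", "Pa s", "Pa s", "s", "Pa", "Pa", "Pa s", "Pa s",
             "Pa")
  )
}

#' @rdname tidy.kv4_fit
#' @method glance kv4_fit
#' @export
glance.kv4_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse, r_squared = x$r_squared, n = x$n, nu = x$nu,
    tau = x$tau, tied = x$tied, boundary = x$boundary
  )
}

#' Tidy a rupture analysis
#'
#' @param x A `rupture_result`.
#' @param ... Unused.
#' @return One row per ramp step: force, count, survival, detached
#'   fraction.
#' @method tidy rupture_result
#' @export
tidy.rupture_result <- function(x, ...) {
  # a trailing post-ramp count row has no force of its own
  force <- c(x$forces, rep(NA_real_, length(x$counts) - length(x$forces)))
  tibble::tibble(
    step = seq_along(x$counts),
    force = force,
    count = x$counts,
    survival = x$survival,
    detached_fraction = x$detached_fraction
  )
}

#' @rdname tidy.rupture_result
#' @method glance rupture_result
#' @export
glance.rupture_result <- function(x, ...) {
  tibble::tibble(
    rupture_force = x$rupture_force,
    rupture_step = x$rupture_step,
    initial_count = x$initial_count,
    final_survival = x$survival[length(x$survival)],
    flagged = x$flagged
  )
}
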