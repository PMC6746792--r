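#' Step-wise flow ramp protocol
#'
#' The bond-strength assay raises the flow rate in equal steps (default
#' 200 to 1400 ul/min in 200 ul/min increments, 30 s per step) so each
#' attached bead experiences a staircase of applied forces. A lead-in
#' window before the first step (default 60 s) brings the recorded window
#' to 270 s and provides the ramp-start attachment count.
#'
#' @param rates Step flow rates, ul/min, strictly increasing.
#' @param step_duration Duration of each step, s.
#' @param lead_in No-flow observation window before the first step, s.
#' @return Object of class `ramp_protocol`: tibble with `step`, `rate`,
#'   `t_start`, `t_end`; total duration as attribute.
#' @export
ramp_protocol <- function(rates = seq(200, 1400, by = 200),
                          step_duration = 30, lead_in = 60) {
  if (any(diff(rates) <= 0)) {
    rlang::abort("`rates` must be strictly increasing.",
                 class = "dorsaflow_argument_error")
  }
  if (step_duration <= 0 || lead_in < 0) {
    rlang::abort("durations must be positive.",
                 class = "dorsaflow_argument_error")
  }
  k <- seq_along(rates)
  steps <- tibble::tibble(
    step = k,
    rate = rates,
    t_start = lead_in + (k - 1) * step_duration,
    t_end = lead_in + k * step_duration
  )
  structure(steps, class = c("ramp_protocol", class(tibble::tibble())),
            step_duration = step_duration, lead_in = lead_in,
            total_duration = lead_in + length(rates) * step_duration)
}

#' Applied force at each ramp step
#'
#' Evaluates one force calibration per step rate at the reference distance
#' `x`, giving the force staircase of the ramp. The schedule is strictly
#' increasing whenever the rate list is.
#'
#' @param protocol A [ramp_protocol()].
#' @param calibrations List of `force_calibration` objects covering every
#'   step rate (matched by `flow_rate`).
#' @param x Centroid-to-wall distance at which forces are evaluated, m.
#' @return Tibble: `step`, `rate` (ul/min), `force` (N).
#' @export
step_force_schedule <- function(protocol, calibrations, x = 5e-6) {
  cal_rates <- vapply(calibrations, function(cal) cal$flow_rate, numeric(1))
  missing_rates <- setdiff(protocol$rate, cal_rates)
  if (length(missing_rates) > 0) {
    rlang::abort(
      paste0("no calibration for flow rate(s): ",
             paste(missing_rates, collapse = ", "), " ul/min"),
      class = "dorsaflow_configuration_error"
    )
  }
  force <- vapply(protocol$rate, function(r) {
    applied_force(x, calibrations[[which(cal_rates == r)[1]]])
  }, numeric(1))
  tibble::tibble(step = protocol$step, rate = protocol$rate, force = force)
}

#' Per-step attachment counts under a flow ramp
#'
#' A bead is counted as attached at the start of step k if it has not
#' detached during any earlier step; detachment during a step is scored as
#' the track ending within that step, or its along-flow displacement within
#' the step exceeding `threshold_um` (default 5 um, far above any creep
#' displacement at these forces -- a detached bead is swept downstream and
#' out of the field). The count for step 1 is taken at ramp start, before
#' any ramp force has acted.
#'
#' @param table A `track_table` whose tracks span the ramp window.
#' @param protocol A [ramp_protocol()].
#' @param threshold_um Within-step along-flow displacement above which a
#'   bead is considered detached, um.
#' @return Integer vector of length `n_steps + 1`: `counts[1]` is the
#'   ramp-start population and `counts[k + 1]` the beads still attached
#'   after step k, so every step's loss is attributable to its force.
#' @export
count_attached <- function(table, protocol, threshold_um = 5) {
  if (nrow(table) == 0) {
    rlang::abort("empty track table.", class = "dorsaflow_data_error")
  }
  fa <- flow_axis(table)
  dt <- frame_interval(table) %||% 1
  n_steps <- nrow(protocol)

  detach_step <- table |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(g, key) {
      s_all <- g$x * fa[1] + g$y * fa[2]
      last_t <- max(g$time)
      det <- Inf
      for (k in seq_len(n_steps)) {
        in_step <- g$time >= protocol$t_start[k] & g$time < protocol$t_end[k]
        ended <- last_t < protocol$t_end[k] - dt / 2
        moved <- if (any(in_step)) {
          s_step <- s_all[in_step]
          max(s_step - s_step[1]) > threshold_um
        } else {
          FALSE
        }
        if (ended || moved) { det <- k; break }
      }
      tibble::tibble(detach_step = det)
    }) |>
    dplyr::bind_rows()

  vapply(seq_len(n_steps + 1), function(k) sum(detach_step$detach_step >= k),
         integer(1))
}

#' Rupture force from per-step attachment counts
#'
#' Survival at step k is S(k) = counts(k) / counts(ramp start). The rupture
#' force is the step force showing the largest fractional single-step loss
#' (S(k) - S(k+1)) / S(k) -- the force at which the largest share of the
#' surviving bond population disengages; the earliest step wins ties. The
#' reported value is the step force, a lower bound on the true threshold
#' within the 30-s step (no interpolation between steps). If no beads
#' detach the result is flagged and the rupture force is NA. Detachment
#' during the final step cannot be attributed (no subsequent count), so a
#' surviving plateau above an early drop is reported as final survival > 0.
#'
#' @param counts Attached counts from [count_attached()]: `counts[1]` at
#'   ramp start, `counts[k]` at the start of step k. Either the same length
#'   as `forces` (the final step's loss is then unobservable) or one longer,
#'   ending with the post-ramp count. Must be non-increasing (re-attachment
#'   is not modelled).
#' @param forces Step forces, N (from [step_force_schedule()]).
#' @return Object of class `rupture_result`: per-step counts, survival,
#'   detached fraction per force, the rupture force and step, the initial
#'   count, and a degenerate-data flag.
#' @export
rupture_force <- function(counts, forces) {
  if (!length(counts) %in% (length(forces) + 0:1)) {
    rlang::abort("`counts` must match `forces` in length (or exceed it by one).",
                 class = "dorsaflow_argument_error")
  }
  if (counts[1] <= 0) {
    rlang::abort("zero initial count.", class = "dorsaflow_data_error")
  }
  if (any(diff(counts) > 0)) {
    rlang::abort("attached counts increased between steps; re-attachment is not modelled.",
                 class = "dorsaflow_data_error")
  }
  K <- length(counts)
  survival <- counts / counts[1]
  # fractional loss of the step-k survivors, attributed to the step-k force
  drop_frac <- c((counts[-K] - counts[-1]) / pmax(counts[-K], 1), NA_real_)
  drop_frac[counts == 0] <- NA_real_

  degenerate <- all(is.na(drop_frac) | drop_frac == 0)
  if (degenerate) {
    rupture_step <- NA_integer_
    rupture <- NA_real_
  } else {
    rupture_step <- which.max(drop_frac)  # earliest max wins
    rupture <- forces[rupture_step]
  }
  structure(
    list(counts = counts, forces = forces, survival = survival,
         detached_fraction = drop_frac, rupture_force = rupture,
         rupture_step = rupture_step, initial_count = counts[1],
         flagged = degenerate),
    class = "rupture_result"
  )
}

#' @export
print.rupture_result <- function(x, ...) {
  if (x$flagged) {
    cat("<rupture_result> no detachment observed; rupture force undefined\n")
  } else {
    cat(sprintf(
      "<rupture_result> rupture force %.3g pN at step %d (%d beads at ramp start, final survival %.2f)\n",
      x$rupture_force * 1e12, x$rupture_step, x$initial_count,
      x$survival[length(x$survival)]
    ))
  }
  invisible(x)
}
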