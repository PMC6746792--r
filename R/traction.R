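#' Cell-medium interface model for bead drag
#'
#' A bead half-enveloped by the plasma membrane translates at the interface
#' between the medium and the cell cortex. At the measurement timescale the
#' cortical actin network behaves as a viscous fluid, so the interfacial
#' drag is Stokes-like with the cortical viscosity and a contact-angle
#' dependent coefficient f(theta). The default contact angle is 90 degrees
#' (beads ~50% enveloped), where f = 0.5 exactly.
#'
#' @param cortical_viscosity Viscosity of the cortical protein network
#'   beneath the membrane, Pa s (default 550).
#' @param contact_angle Contact angle theta between particle, cell and
#'   medium, radians in (0, pi).
#' @return List of class `interface_model` with the precomputed drag
#'   coefficient `f`.
#' @export
interface_model <- function(cortical_viscosity = 550, contact_angle = pi / 2) {
  if (cortical_viscosity <= 0) {
    rlang::abort("`cortical_viscosity` must be positive.",
                 class = "dorsaflow_argument_error")
  }
  structure(
    list(cortical_viscosity = cortical_viscosity,
         contact_angle = contact_angle,
         f = interfacial_drag_coefficient(contact_angle)),
    class = "interface_model"
  )
}

#' Drag coefficient of a translating interfacial particle
#'
#' f(theta) = 0.5 [1 + (9/16) cos(theta) - 0.139 cos^2(theta)] for a sphere
#' translating along a fluid-fluid interface with contact angle theta.
#' f(pi/2) = 0.5. Over theta in `[pi/3, 2pi/3]` f deviates from f(pi/2) by
#' up to ~32%, which bounds the error incurred by assuming a 90-degree
#' contact angle.
#'
#' @param theta Contact angle, radians, in (0, pi); vectorised.
#' @return Drag coefficient f.
#' @export
interfacial_drag_coefficient <- function(theta) {
  if (any(theta <= 0 | theta >= pi)) {
    rlang::abort("`theta` must lie in (0, pi).",
                 class = "dorsaflow_domain_error")
  }
  0.5 * (1 + 9 / 16 * cos(theta) - 0.139 * cos(theta)^2)
}

#' Interfacial drag force on a moving bead
#'
#' F_D = 6 pi a mu_c u f(theta): the drag a cell-bound bead must overcome to
#' translate through the membrane/cortex interface at speed u.
#'
#' @param u Bead speed, m/s (>= 0); vectorised.
#' @param iface An [interface_model()].
#' @param particle A [particle_properties()].
#' @return Interfacial drag force, N.
#' @export
interfacial_drag <- function(u, iface = interface_model(),
                             particle = particle_properties()) {
  if (any(u < 0)) {
    rlang::abort("`u` must be non-negative.",
                 class = "dorsaflow_argument_error")
  }
  6 * pi * particle$radius * iface$cortical_viscosity * u * iface$f
}

#' Dorsal traction force from a single bead trajectory
#'
#' Scalar force balance along the flow axis: a cell pulling a bound bead
#' against the flow must overcome both the applied hydrodynamic force and
#' the interfacial drag, so the traction magnitude is F_C = F_A + F_D with
#' F_D evaluated at the bead's fitted speed. The balance presumes motion
#' opposing the flow; beads moving with the flow yield a flagged result
#' with F_C unset rather than a negative traction.
#'
#' @param traj Single-track data frame (`time`, `x`, `y`), passing velocity
#'   QC (>= 5 samples).
#' @param F_A Applied hydrodynamic force at the bead, N (from
#'   [applied_force()] at the reference height).
#' @param iface An [interface_model()].
#' @param particle A [particle_properties()].
#' @param flow_axis Unit flow vector; defaults to the track attribute.
#' @return One-row tibble: `track_id`, `u` (m/s), `F_A`, `F_D`, `F_C` (N),
#'   `direction` ("against"/"with"), `r_squared`, `flagged`.
#' @export
traction_force <- function(traj, F_A, iface = interface_model(),
                           particle = particle_properties(),
                           flow_axis = NULL) {
  series <- project_displacement(traj, flow_axis = flow_axis)
  vel <- estimate_velocity(series)
  u <- vel$speed
  f_d <- interfacial_drag(u, iface, particle)
  # a stationary bead has F_D = 0, so the balance degenerates to F_C = F_A
  stationary <- u == 0
  against <- vel$sign < 0 | stationary
  tibble::tibble(
    track_id = if ("track_id" %in% names(traj)) traj$track_id[1] else NA,
    u = u,
    F_A = F_A,
    F_D = f_d,
    F_C = ifelse(against, F_A + f_d, NA_real_),
    direction = dplyr::case_when(stationary ~ "stationary",
                                 against ~ "against",
                                 .default = "with"),
    r_squared = vel$r_squared,
    flagged = vel$flagged | !against
  )
}

#' Dorsal traction forces for every track in a table
#'
#' Applies [traction_force()] per track. Tracks failing velocity QC are
#' reported with NA forces and `flagged = TRUE` instead of stopping the
#' batch.
#'
#' @inheritParams traction_force
#' @param table A `track_table`.
#' @return Tibble, one row per track.
#' @export
traction_forces <- function(table, F_A, iface = interface_model(),
                            particle = particle_properties()) {
  fa <- flow_axis(table)
  table |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(g, key) {
      g$track_id <- key$track_id
      tryCatch(
        traction_force(g, F_A, iface, particle, flow_axis = fa),
        dorsaflow_qc_error = function(e) tibble::tibble(
          track_id = key$track_id, u = NA_real_, F_A = F_A, F_D = NA_real_,
          F_C = NA_real_, direction = NA_character_, r_squared = NA_real_,
          flagged = TRUE
        )
      )
    }) |>
    dplyr::bind_rows()
}

#' Magnetic force calibration from free-bead tracks
#'
#' In the magnetic-tweezers comparison mode the applied force is magnetic
#' rather than hydrodynamic; it is calibrated by assuming the magnetic force
#' on a free (unbound) bead equals the wall-corrected Stokes drag at its
#' observed speed, F_M = 6 pi a mu u C. The traction balance F_C = F_M + F_D
#' is then structurally identical to the flow case, so the calibrated F_M
#' feeds [traction_force()] directly as its `F_A` argument.
#'
#' @param free_tracks `track_table` of free-moving beads (>= 5 samples each).
#' @param ctx A [hydro_context()].
#' @return Tibble: `track_id`, `u` (m/s), `F_M` (N), `r_squared`.
#' @export
magnetic_force_calibration <- function(free_tracks, ctx = hydro_context()) {
  fa <- flow_axis(free_tracks)
  free_tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(g, key) {
      series <- project_displacement(g, flow_axis = fa)
      vel <- estimate_velocity(series)
      tibble::tibble(
        track_id = key$track_id,
        u = vel$speed,
        F_M = 6 * pi * ctx$particle$radius * ctx$fluid$viscosity *
          vel$speed * ctx$correction,
        r_squared = vel$r_squared
      )
    }) |>
    dplyr::bind_rows()
}
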