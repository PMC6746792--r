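#' Channel, fluid and particle descriptors
#'
#' Constructors for the physical context of the force calibration. Defaults
#' describe the measurement rig: a 1 mm x 100 um rectangular channel, an
#' aqueous medium, and 2.8-um superparamagnetic beads (density ~1.3 g/ml).
#' All quantities are SI.
#'
#' @param width Channel width w, m.
#' @param height Channel height H, m.
#' @return `channel_geometry()`: list with `width`, `height`.
#' @export
channel_geometry <- function(width = 1e-3, height = 1e-4) {
  if (!(width > height && height > 0)) {
    rlang::abort("require width > height > 0.",
                 class = "dorsaflow_argument_error")
  }
  structure(list(width = width, height = height),
            class = "channel_geometry")
}

#' @rdname channel_geometry
#' @param viscosity Dynamic viscosity mu, Pa s.
#' @param density Fluid density rho, kg/m^3.
#' @export
fluid_properties <- function(viscosity = 1e-3, density = 1000) {
  if (viscosity <= 0 || density <= 0) {
    rlang::abort("fluid properties must be positive.",
                 class = "dorsaflow_argument_error")
  }
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}

#' @rdname channel_geometry
#' @param diameter Particle diameter d, m.
#' @param material_density Particle material density, kg/m^3.
#' @export
particle_properties <- function(diameter = 2.8e-6, material_density = 1300) {
  if (diameter <= 0 || material_density <= 0) {
    rlang::abort("particle properties must be positive.",
                 class = "dorsaflow_argument_error")
  }
  a <- diameter / 2
  structure(
    list(diameter = diameter, radius = a, material_density = material_density,
         mass = material_density * 4 / 3 * pi * a^3),
    class = "particle_properties"
  )
}

#' Hydrodynamic context
#'
#' Bundles geometry, fluid and particle with the reference height `h`: the
#' distance of a cell-bound bead's centroid from the channel floor. Cell
#' heights range from roughly 3 to 8 um and the wall correction varies
#' little over that band, so a universal h = 5 um is used by default; the
#' wall-correction factor C is precomputed at that height.
#'
#' @param geometry A [channel_geometry()].
#' @param fluid A [fluid_properties()].
#' @param particle A [particle_properties()].
#' @param h Reference height of the particle centroid above the floor, m.
#' @return List of class `hydro_context` with element `correction` = C(d, h).
#' @export
hydro_context <- function(geometry = channel_geometry(),
                          fluid = fluid_properties(),
                          particle = particle_properties(),
                          h = 5e-6) {
  if (h <= 0 || h >= geometry$height) {
    rlang::abort("`h` must lie inside the channel.",
                 class = "dorsaflow_argument_error")
  }
  structure(
    list(geometry = geometry, fluid = fluid, particle = particle, h = h,
         correction = wall_correction_factor(particle$diameter, h)),
    class = "hydro_context"
  )
}

ul_min_to_m3_s <- function(Q) Q * 1e-9 / 60

#' Laminar channel velocity profile
#'
#' Fully developed parallel-plate Poiseuille profile for the central region
#' of a wide shallow channel (aspect ratio 10:1; measurements are restricted
#' to > 200 um from the side walls, where this profile is accurate):
#' u(z) = 6 u_mean (z/H)(1 - z/H) with u_mean = Q / (w H). No-slip holds at
#' both plates.
#'
#' @param z Wall-normal position(s), m, in `[0, H]`.
#' @param Q Volumetric flow rate, ul/min.
#' @param geometry A [channel_geometry()].
#' @param fluid A [fluid_properties()] (carried for signature symmetry; the
#'   profile at fixed Q is viscosity-independent).
#' @return Streamwise fluid velocity, m/s.
#' @export
channel_velocity <- function(z, Q, geometry = channel_geometry(),
                             fluid = fluid_properties()) {
  H <- geometry$height
  if (any(z < 0 | z > H)) {
    rlang::abort("`z` outside [0, H].", class = "dorsaflow_argument_error")
  }
  if (Q <= 0) {
    rlang::abort("`Q` must be positive.", class = "dorsaflow_argument_error")
  }
  u_mean <- ul_min_to_m3_s(Q) / (geometry$width * H)
  6 * u_mean * (z / H) * (1 - z / H)
}

#' Wall correction factor for near-wall Stokes drag
#'
#' Faxen-type polynomial correction for a sphere of diameter d translating
#' parallel to a plane wall with its centroid a distance h from the wall:
#' \deqn{C = [1 - (9/16)r + (1/8)r^3 - (45/256)r^4 - (1/16)r^5]^{-1}, \quad
#'   r = d/(2h).}
#' C -> 1 in the free-stream limit and grows monotonically as the particle
#' approaches the wall; at d = 2.8 um, h = 5 um it evaluates to 1.185.
#'
#' @param d Particle diameter, m.
#' @param h Centroid-to-wall distance, m. Requires 0 < d/(2h) <= 1.
#' @return Correction factor C >= 1 (vectorised over `h`).
#' @export
wall_correction_factor <- function(d, h) {
  r <- d / (2 * h)
  if (any(r <= 0)) {
    rlang::abort("require d > 0 and finite h.",
                 class = "dorsaflow_domain_error")
  }
  if (any(r > 1)) {
    rlang::abort("d/(2h) > 1: particle centroid below contact height.",
                 class = "dorsaflow_domain_error")
  }
  1 / (1 - 9 / 16 * r + 1 / 8 * r^3 - 45 / 256 * r^4 - 1 / 16 * r^5)
}

#' Schiller-Naumann drag coefficient
#'
#' Empirical extension of Stokes drag to finite particle Reynolds number:
#' C_D = (24 / Re_p)(1 + 0.15 Re_p^0.687). C_D Re_p -> 24 recovers the
#' Stokes limit as Re_p -> 0.
#'
#' @param re_p Particle Reynolds number (> 0).
#' @return Drag coefficient C_D.
#' @export
schiller_naumann_cd <- function(re_p) {
  if (any(re_p <= 0)) {
    rlang::abort("`re_p` must be positive.", class = "dorsaflow_domain_error")
  }
  24 / re_p * (1 + 0.15 * re_p^0.687)
}

# Schiller-Naumann inertial multiplier on the Stokes force; identity below
# re_min where the correction is negligible.
sn_multiplier <- function(re_p, re_min = 1e-3) {
  ifelse(re_p > re_min, 1 + 0.15 * re_p^0.687, 1)
}

#' Advect a particle to terminal velocity at fixed height
#'
#' Integrates the particle transport equation
#' \deqn{m \, dV_p/dt = (1/8) \pi \rho_f d_p^2 C_D |V_f - V_p| (V_f - V_p)}
#' with the Schiller-Naumann drag coefficient, at fixed wall-normal height z
#' (no lift, gravity or Brownian term), with the local fluid velocity from
#' [channel_velocity()]. The momentum relaxation time m/(3 pi mu d) is of
#' order microseconds for these beads, so the terminal state -- where the
#' particle velocity equals the local fluid velocity -- is reached almost
#' immediately. Integration is explicit with `dt` defaulting to
#' min(1e-5 s, relaxation time) and stops when the slip ratio
#' |V_f - V_p| / |V_f| falls below `tol`.
#'
#' @param z Wall-normal height, m, strictly inside the channel.
#' @param Q Flow rate, ul/min.
#' @param ctx A [hydro_context()].
#' @param duration Maximum integration time, s.
#' @param dt Time step, s; default min(1e-5, relaxation time).
#' @param v0 Initial particle velocity, m/s.
#' @param tol Convergence tolerance on the slip ratio.
#' @return One-row tibble: `z`, `v_p`, `v_f`, `re_p`, `c_d`, `slip_ratio`,
#'   `steps`.
#' @export
advect_particle <- function(z, Q, ctx = hydro_context(), duration = 0.05,
                            dt = NULL, v0 = 0, tol = 1e-4) {
  H <- ctx$geometry$height
  if (z <= 0 || z >= H) {
    rlang::abort("`z` must be strictly inside (0, H).",
                 class = "dorsaflow_argument_error")
  }
  mu <- ctx$fluid$viscosity
  rho <- ctx$fluid$density
  d <- ctx$particle$diameter
  m <- ctx$particle$mass
  v_f <- channel_velocity(z, Q, ctx$geometry, ctx$fluid)
  tau_relax <- m / (3 * pi * mu * d)
  if (is.null(dt)) dt <- min(1e-5, tau_relax)

  v_p <- v0
  n_max <- ceiling(duration / dt)
  steps <- 0L
  slip_ratio <- abs(v_f - v_p) / abs(v_f)
  while (slip_ratio >= tol && steps < n_max) {
    slip <- v_f - v_p
    re_p <- rho * d * abs(slip) / mu
    # (1/8) pi rho d^2 C_D |slip| slip reduces to 3 pi mu d (1 + 0.15 Re^0.687) slip
    f <- 3 * pi * mu * d * sn_multiplier(re_p, re_min = 0) * slip
    v_p <- v_p + dt * f / m
    steps <- steps + 1L
    slip_ratio <- abs(v_f - v_p) / abs(v_f)
  }
  if (slip_ratio >= tol) {
    rlang::abort(
      sprintf("advection did not converge within %g s (slip ratio %.3g)",
              duration, slip_ratio),
      class = "dorsaflow_convergence_error"
    )
  }
  re_p <- rho * d * abs(v_f - v_p) / mu
  tibble::tibble(
    z = z, v_p = v_p, v_f = v_f, re_p = re_p,
    c_d = ifelse(re_p > 0, schiller_naumann_cd(re_p), NA_real_),
    slip_ratio = slip_ratio, steps = steps
  )
}

#' Wall-corrected Stokes drag on a particle
#'
#' Modified Stokes law F_A = 6 pi a mu u C, with the wall-correction factor
#' C from the context's reference height. For particle Reynolds numbers
#' above 1e-3 the Schiller-Naumann inertial multiplier
#' (1 + 0.15 Re_p^0.687) is applied for continuity with the advection model;
#' below that the correction is negligible and the pure Stokes form is used.
#'
#' @param u Particle speed relative to the fluid, m/s (>= 0); vectorised.
#' @param ctx A [hydro_context()].
#' @return Drag force, N.
#' @export
drag_force <- function(u, ctx = hydro_context()) {
  if (any(u < 0)) {
    rlang::abort("`u` must be non-negative.",
                 class = "dorsaflow_argument_error")
  }
  mu <- ctx$fluid$viscosity
  re_p <- ctx$fluid$density * ctx$particle$diameter * u / mu
  6 * pi * ctx$particle$radius * mu * u * ctx$correction * sn_multiplier(re_p)
}

#' Default calibration height grid
#'
#' Nine wall-normal heights spanning the near-wall region (where cell-bound
#' beads sit) up to mid-channel, m.
#' @export
default_heights <- function() {
  c(2, 3, 5, 8, 12, 18, 25, 35, 50) * 1e-6
}

#' Build the applied-force calibration at one flow rate
#'
#' The semi-analytic replacement for the CFD calibration stage: at each
#' height of the grid a particle is advected to terminal velocity, the
#' wall-corrected drag at that height is computed (the correction factor is
#' evaluated per height, not at the universal reference), and the resulting
#' force-versus-distance samples are fitted to the four-parameter logistic
#' \deqn{F(x) = (A_1 - A_2) / (1 + (x/x_0)^p) + A_2}
#' by nonlinear least squares (5 restarts with jittered x0 under a fixed
#' internal seed; best SSE wins; p bounded in (0, 10]). The fit is required
#' to reach r-squared > `r2_min`.
#'
#' @param Q Flow rate, ul/min.
#' @param ctx A [hydro_context()].
#' @param heights Height grid, m; at least 6 values spanning near-wall to
#'   mid-channel.
#' @param r2_min Minimum acceptable r-squared (default 0.95).
#' @return Object of class `force_calibration`: flow rate, the (x, F)
#'   samples, logistic parameters `A1`, `A2` (N), `x0` (m), `p`, and
#'   `r_squared`.
#' @export
build_calibration <- function(Q, ctx = hydro_context(),
                              heights = default_heights(), r2_min = 0.95) {
  if (length(heights) < 6) {
    rlang::abort("need >= 6 calibration heights.",
                 class = "dorsaflow_argument_error")
  }
  heights <- sort(heights)
  samples <- purrr::map_dfr(heights, function(h) {
    st <- advect_particle(h, Q, ctx)
    ctx_h <- ctx
    ctx_h$correction <- wall_correction_factor(ctx$particle$diameter, h)
    tibble::tibble(x = h, v = st$v_p, F = drag_force(st$v_p, ctx_h))
  })
  fit <- fit_logistic(samples$x, samples$F)
  if (!fit$converged || fit$r_squared <= r2_min) {
    rlang::abort(
      sprintf("logistic calibration failed (r2 = %.4f); residual range [%.3g, %.3g] N",
              fit$r_squared, min(fit$residuals), max(fit$residuals)),
      class = "dorsaflow_calibration_error"
    )
  }
  structure(
    list(flow_rate = Q, samples = samples,
         A1 = fit$A1, A2 = fit$A2, x0 = fit$x0, p = fit$p,
         r_squared = fit$r_squared, ctx = ctx),
    class = "force_calibration"
  )
}

# Logistic fit in scaled units (um, pN) for conditioning; multi-start with
# jittered x0, fixed local seed, best SSE wins.
fit_logistic <- function(x_m, F_N, restarts = 5) {
  df <- data.frame(x = x_m * 1e6, F = F_N * 1e12)
  base_start <- list(A1 = min(df$F), A2 = max(df$F),
                     x0 = stats::median(df$x), p = 2)
  lower <- c(-Inf, -Inf, 1e-3, 1e-3)
  upper <- c(Inf, Inf, 1e4, 10)
  jitters <- withr::with_seed(181, stats::rlnorm(restarts, 0, 0.4))
  best <- NULL
  for (j in jitters) {
    st <- base_start
    st$x0 <- base_start$x0 * j
    fit <- tryCatch(
      minpack.lm::nlsLM(F ~ (A1 - A2) / (1 + (x / x0)^p) + A2, data = df,
                        start = st, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(list(converged = FALSE, r_squared = NA_real_, residuals = NA_real_))
  }
  cf <- stats::coef(best$fit)
  r2 <- 1 - best$sse / sum((df$F - mean(df$F))^2)
  list(
    converged = TRUE,
    A1 = unname(cf["A1"]) * 1e-12, A2 = unname(cf["A2"]) * 1e-12,
    x0 = unname(cf["x0"]) * 1e-6, p = unname(cf["p"]),
    r_squared = r2, residuals = stats::residuals(best$fit) * 1e-12
  )
}

#' @export
print.force_calibration <- function(x, ...) {
  cat(sprintf(
    "<force_calibration> Q = %g ul/min | F(5 um) = %.3g pN | r2 = %.4f\n",
    x$flow_rate, applied_force(5e-6, x) * 1e12, x$r_squared
  ))
  invisible(x)
}

#' Evaluate the fitted force-distance calibration
#'
#' Substitutes a centroid-to-wall distance into the fitted logistic to give
#' the applied hydrodynamic force at that distance. Warns when `x` lies
#' outside the calibrated sample span.
#'
#' @param x Distance from the bottom wall, m (vectorised).
#' @param cal A `force_calibration` from [build_calibration()].
#' @return Applied force, N.
#' @export
applied_force <- function(x, cal) {
  rng <- range(cal$samples$x)
  if (any(x < rng[1] | x > rng[2])) {
    rlang::warn("evaluating the calibration outside its sample span",
                class = "dorsaflow_extrapolation_warning")
  }
  (cal$A1 - cal$A2) / (1 + (x / cal$x0)^cal$p) + cal$A2
}

#' Ligand count conjugated per particle
#'
#' Bead-stock accounting: the mass of IgG bound per mg of beads, the ligand
#' molecular weight and the number of particles per mg give the number of
#' ligand molecules per particle (reported to one significant figure, as the
#' quantity is an order-of-magnitude estimate).
#'
#' @param bound_mass_ug Ligand mass bound per mg of particles, ug.
#' @param mw_g_mol Ligand molecular weight, g/mol.
#' @param particles_per_mg Particles per mg of stock.
#' @return List: `molecules` (total per mg) and `per_particle` (rounded to
#'   one significant figure).
#' @export
ligands_per_particle <- function(bound_mass_ug = 8, mw_g_mol = 150,
                                 particles_per_mg = 6.09e8) {
  if (bound_mass_ug <= 0 || mw_g_mol <= 0 || particles_per_mg <= 0) {
    rlang::abort("all inputs must be positive.",
                 class = "dorsaflow_argument_error")
  }
  n_avogadro <- 6.02214076e23
  molecules <- bound_mass_ug * 1e-6 / mw_g_mol * n_avogadro
  list(molecules = molecules,
       per_particle = signif(molecules / particles_per_mg, 1))
}
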