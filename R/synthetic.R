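#' Synthetic traction-mode trajectories with ground truth
#'
#' Emulates the traction assay: beads bound to contractile cells under a
#' weak flow move against the flow direction at constant speed. Per-bead
#' speeds are drawn log-normally (median `speed_median`, log-sd
#' `sigma_log`); i.i.d. Gaussian localisation noise is added to both
#' coordinates each frame. The truth table carries each bead's speed and
#' the implied traction force F_C = F_A + F_D, so the full pipeline can be
#' validated end to end against known values.
#'
#' @param n Number of beads.
#' @param speed_median Median bead speed, m/s.
#' @param sigma_log Log-sd of the speed distribution.
#' @param noise_sd Localisation noise, m (default 50 nm, ~0.1 px at 10X).
#' @param frame_interval Imaging interval, s (traction protocol: 10 s).
#' @param duration Recording length, s (traction protocol: 300 s).
#' @param F_A Applied hydrodynamic force, N; by default computed from the
#'   semi-analytic model at `Q` ul/min and the context's reference height.
#' @param Q Flow rate used when `F_A` is not supplied, ul/min.
#' @param iface An [interface_model()].
#' @param ctx A [hydro_context()].
#' @param flow_axis Unit flow vector in image coordinates.
#' @param seed Integer seed; output is bit-reproducible for a fixed seed.
#' @return List with `tracks` (a `track_table`) and `truth` (tibble:
#'   `track_id`, `u_true`, `F_A`, `F_D_true`, `F_C_true`).
#' @export
gen_traction_tracks <- function(n = 50, speed_median = 2e-8, sigma_log = 0.3,
                                noise_sd = 5e-8, frame_interval = 10,
                                duration = 300, F_A = NULL, Q = 10,
                                iface = interface_model(),
                                ctx = hydro_context(),
                                flow_axis = c(1, 0), seed = 1) {
  if (is.null(F_A)) F_A <- terminal_drag(Q, ctx)
  flow_axis <- normalize_flow_axis(flow_axis)
  times <- seq(0, duration, by = frame_interval)

  withr::with_seed(seed, {
    u <- stats::rlnorm(n, log(speed_median), sigma_log)
    x0 <- stats::runif(n, 100, 600)
    y0 <- stats::runif(n, 100, 600)
    spots <- purrr::map_dfr(seq_len(n), function(i) {
      s_um <- -u[i] * 1e6 * times  # against the flow
      tibble::tibble(
        track_id = i,
        frame = seq_along(times) - 1,
        time = times,
        x = x0[i] + s_um * flow_axis[1] + stats::rnorm(length(times), 0, noise_sd * 1e6),
        y = y0[i] + s_um * flow_axis[2] + stats::rnorm(length(times), 0, noise_sd * 1e6),
        wall_distance = 500
      )
    })
  })

  f_d <- interfacial_drag(u, iface, ctx$particle)
  list(
    tracks = track_table(spots, frame_interval, pixel_size = 1,
                         flow_axis = flow_axis),
    truth = tibble::tibble(track_id = seq_len(n), u_true = u, F_A = F_A,
                           F_D_true = f_d, F_C_true = F_A + f_d)
  )
}

# Terminal-velocity drag at the context's reference height for flow rate Q.
terminal_drag <- function(Q, ctx = hydro_context()) {
  drag_force(advect_particle(ctx$h, Q, ctx)$v_p, ctx)
}

#' Synthetic creep-and-recovery trajectories with ground truth
#'
#' Emulates the viscoelasticity assay: a constant force switches on at
#' `flow_on` and off at `flow_off`; bead displacement follows the
#' four-element creep compliance during loading and linear superposition
#' during recovery, scaled by F_A / (6 pi a C). Per-cell parameters are
#' log-normally scattered around `center` with mean preserved (so the
#' cohort-mean instantaneous stiffness E_0 + E_1 is 2(G_0+G_1)(1+nu) ~
#' 1.96 kPa at nu = 0.4 for the default centre). The flow-onset frame
#' records zero displacement (it precedes loading).
#'
#' @param n Number of cells.
#' @param center Named vector of central parameters `G0`, `G1` (Pa),
#'   `mu0p`, `mu1p` (Pa s).
#' @param sigma_log Log-sd of the per-cell parameter scatter.
#' @param noise_sd Localisation noise, m.
#' @param frame_interval Imaging interval, s (viscoelastic protocol: 0.5 s).
#' @param duration Recording length, s (protocol: 180 s).
#' @param flow_on,flow_off Load window, s.
#' @param F_A Applied force, N; default from the semi-analytic model at `Q`.
#' @param Q Flow rate used when `F_A` is not supplied, ul/min.
#' @param ctx A [hydro_context()].
#' @param flow_axis Unit flow vector.
#' @param seed Integer seed.
#' @return List with `tracks` and `truth` (per-cell parameters and
#'   `E0_plus_E1_true` at nu = 0.4).
#' @export
gen_creep_tracks <- function(n = 50,
                             center = c(G0 = 500, G1 = 200,
                                        mu0p = 550, mu1p = 50),
                             sigma_log = 0.3, noise_sd = 5e-8,
                             frame_interval = 0.5, duration = 180,
                             flow_on = 10, flow_off = 100,
                             F_A = NULL, Q = 1000,
                             ctx = hydro_context(), flow_axis = c(1, 0),
                             seed = 1) {
  if (is.null(F_A)) F_A <- terminal_drag(Q, ctx)
  flow_axis <- normalize_flow_axis(flow_axis)
  times <- seq(0, duration, by = frame_interval)
  scale <- F_A / (6 * pi * ctx$particle$radius * ctx$correction)
  t_on <- flow_off - flow_on

  withr::with_seed(seed, {
    # mean-preserving log-normal scatter: E[exp(N(-s^2/2, s^2))] = 1
    pars <- purrr::map(names(center), function(p) {
      center[[p]] * stats::rlnorm(n, -sigma_log^2 / 2, sigma_log)
    })
    names(pars) <- names(center)
    x0 <- stats::runif(n, 100, 600)
    y0 <- stats::runif(n, 100, 600)
    spots <- purrr::map_dfr(seq_len(n), function(i) {
      J <- function(t) kv4_compliance(t, pars$G0[i], pars$G1[i],
                                      pars$mu0p[i], pars$mu1p[i])
      X <- numeric(length(times))
      creep <- times > flow_on & times <= flow_off
      recov <- times > flow_off
      X[creep] <- scale * J(times[creep] - flow_on)
      tp <- times[recov] - flow_off
      X[recov] <- scale * (J(t_on + tp) - J(tp))
      s_um <- X * 1e6  # displacement along the flow, um
      tibble::tibble(
        track_id = i,
        frame = seq_along(times) - 1,
        time = times,
        x = x0[i] + s_um * flow_axis[1] + stats::rnorm(length(times), 0, noise_sd * 1e6),
        y = y0[i] + s_um * flow_axis[2] + stats::rnorm(length(times), 0, noise_sd * 1e6),
        wall_distance = 500
      )
    })
  })

  truth <- tibble::tibble(
    track_id = seq_len(n),
    G0_true = pars$G0, G1_true = pars$G1,
    mu0p_true = pars$mu0p, mu1p_true = pars$mu1p,
    tau_true = kv4_tau(pars$G0, pars$G1, pars$mu1p),
    E0_plus_E1_true = convert_moduli(pars$G0 + pars$G1, 0.4),
    F_A = F_A
  )
  list(
    tracks = track_table(spots, frame_interval, pixel_size = 1,
                         flow_axis = flow_axis),
    truth = truth
  )
}

#' Synthetic flow-ramp trajectories with rupture ground truth
#'
#' Emulates the bond-strength assay: each bead carries a rupture threshold
#' drawn from a mixture distribution and detaches -- its track ends at a
#' random time within the step -- at the first ramp step whose force
#' exceeds that threshold. Attached beads show only bounded localisation
#' jitter, far below the detachment displacement rule.
#'
#' Mixture presets (component sizes are fixed counts, log-normal scatter
#' within components, so the population fractions are exact by design):
#' \describe{
#'   \item{`"integrin"`}{27% of thresholds between the step-1 and step-2
#'     forces, 73% above the maximum ramp force: a sharp loss at step 2
#'     followed by a surviving plateau.}
#'   \item{`"cd80"`}{90% of thresholds below the step-1 force, 10% above
#'     the maximum: a sharp loss at the first step.}
#' }
#'
#' @param n Number of beads.
#' @param protocol A [ramp_protocol()].
#' @param forces Step forces, N; by default the terminal-velocity drag at
#'   each step rate at the context's reference height.
#' @param mixture `"integrin"`, `"cd80"`, or `"manual"` (supply
#'   `thresholds`).
#' @param thresholds Optional explicit per-bead rupture thresholds, N
#'   (length `n`); overrides `mixture`.
#' @param noise_sd Localisation noise, m.
#' @param frame_interval Imaging interval, s (ramp protocol: 1 s).
#' @param ctx A [hydro_context()].
#' @param flow_axis Unit flow vector.
#' @param seed Integer seed.
#' @return List with `tracks`, `truth` (`track_id`, `threshold`,
#'   `detach_step_true`, Inf when never detaching) and the `forces` used.
#' @export
gen_ramp_tracks <- function(n = 50, protocol = ramp_protocol(),
                            forces = NULL, mixture = c("integrin", "cd80", "manual"),
                            thresholds = NULL, noise_sd = 5e-8,
                            frame_interval = 1, ctx = hydro_context(),
                            flow_axis = c(1, 0), seed = 1) {
  mixture <- match.arg(mixture)
  flow_axis <- normalize_flow_axis(flow_axis)
  if (is.null(forces)) {
    forces <- vapply(protocol$rate, terminal_drag, numeric(1), ctx = ctx)
  }
  K <- length(forces)
  duration <- attr(protocol, "total_duration")
  times <- seq(0, duration, by = frame_interval)

  withr::with_seed(seed, {
    if (is.null(thresholds)) {
      thresholds <- ramp_thresholds(n, forces, mixture)
    } else if (length(thresholds) != n) {
      rlang::abort("`thresholds` must have length `n`.",
                   class = "dorsaflow_argument_error")
    }
    detach_step <- vapply(thresholds, function(T_i) {
      k <- which(forces > T_i)[1]
      if (is.na(k)) Inf else as.numeric(k)
    }, numeric(1))

    x0 <- stats::runif(n, 100, 600)
    y0 <- stats::runif(n, 100, 600)
    t_detach <- ifelse(
      is.infinite(detach_step), Inf,
      protocol$t_start[pmin(detach_step, K)] +
        (0.3 + 0.6 * stats::runif(n)) * attr(protocol, "step_duration")
    )
    spots <- purrr::map_dfr(seq_len(n), function(i) {
      tt <- times[times < t_detach[i]]
      tibble::tibble(
        track_id = i,
        frame = match(tt, times) - 1,
        time = tt,
        x = x0[i] + stats::rnorm(length(tt), 0, noise_sd * 1e6),
        y = y0[i] + stats::rnorm(length(tt), 0, noise_sd * 1e6),
        wall_distance = 500
      )
    })
  })

  list(
    tracks = track_table(spots, frame_interval, pixel_size = 1,
                         flow_axis = flow_axis),
    truth = tibble::tibble(track_id = seq_len(n), threshold = thresholds,
                           detach_step_true = detach_step),
    forces = forces
  )
}

# Stratified mixture thresholds; called inside the generator's seeded block.
ramp_thresholds <- function(n, forces, mixture) {
  f1 <- forces[1]
  f_max <- forces[length(forces)]
  if (mixture == "integrin") {
    f2 <- forces[2]
    n_low <- round(0.27 * n)
    low <- stats::rlnorm(n_low, log(sqrt(f1 * f2)), 0.1)
    low <- pmin(pmax(low, 1.02 * f1), 0.98 * f2)
    high <- pmax(stats::rlnorm(n - n_low, log(3 * f_max), 0.2), 1.1 * f_max)
  } else if (mixture == "cd80") {
    n_low <- round(0.9 * n)
    low <- stats::rlnorm(n_low, log(0.7 * f1), 0.15)
    low <- pmin(low, 0.95 * f1)
    high <- pmax(stats::rlnorm(n - n_low, log(3 * f_max), 0.2), 1.1 * f_max)
  } else {
    rlang::abort("mixture = \"manual\" requires explicit `thresholds`.",
                 class = "dorsaflow_argument_error")
  }
  sample(c(low, high))
}

#' Render a track table as a synthetic 16-bit image stack
#'
#' Places a Gaussian spot at each bead position per frame on a constant
#' background, applies Poisson shot noise, and optionally writes a
#' multi-page 16-bit TIFF. Intended to exercise the minimal tracking
#' front-end ([detect_and_link()]); it is not a photorealistic bright-field
#' renderer.
#'
#' @param table A `track_table` (positions in um).
#' @param shape Image size, pixels, `c(ny, nx)`.
#' @param pixel_size Micrometres per pixel used to map positions to pixels.
#' @param psf_sigma Spot Gaussian sigma, pixels.
#' @param background Constant background, counts.
#' @param amplitude Spot peak amplitude, counts.
#' @param poisson Apply Poisson shot noise?
#' @param seed Integer seed (shot noise).
#' @param path Optional output TIFF path.
#' @return 3-D array `[ny, nx, n_frames]` of counts (invisibly if written),
#'   with `pixel_size` and `frame_interval` attributes.
#' @export
gen_image_stack <- function(table, shape = c(64, 64), pixel_size = 1,
                            psf_sigma = 1.5, background = 100,
                            amplitude = 2000, poisson = TRUE, seed = 1,
                            path = NULL) {
  frames <- sort(unique(table$frame))
  ny <- shape[1]; nx <- shape[2]
  cx_all <- table$x / pixel_size
  cy_all <- table$y / pixel_size
  clipped <- cx_all < 0 | cx_all > nx | cy_all < 0 | cy_all > ny
  if (any(clipped)) {
    rlang::warn(sprintf("%d spot position(s) outside the frame were clipped",
                        sum(clipped)))
  }
  xs <- seq_len(nx) - 0.5
  ys <- seq_len(ny) - 0.5
  stack <- array(0, dim = c(ny, nx, length(frames)))
  for (fi in seq_along(frames)) {
    img <- matrix(background, ny, nx)
    rows <- which(table$frame == frames[fi])
    for (r in rows) {
      cx <- min(max(cx_all[r], 0), nx)
      cy <- min(max(cy_all[r], 0), ny)
      gx <- exp(-(xs - cx)^2 / (2 * psf_sigma^2))
      gy <- exp(-(ys - cy)^2 / (2 * psf_sigma^2))
      img <- img + amplitude * outer(gy, gx)
    }
    stack[, , fi] <- img
  }
  if (poisson) {
    stack[] <- withr::with_seed(seed, stats::rpois(length(stack), stack))
  }
  stack[] <- pmin(round(stack), 65535)
  attr(stack, "pixel_size") <- pixel_size
  attr(stack, "frame_interval") <- frame_interval(table) %||% 1
  if (!is.null(path)) {
    pages <- lapply(seq_len(dim(stack)[3]), function(fi) stack[, , fi] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    return(invisible(stack))
  }
  stack
}

#' Minimal spot detection and nearest-neighbour linking
#'
#' A deliberately small stand-in for a full tracking suite, sufficient for
#' the synthetic stacks produced by [gen_image_stack()]: per frame, spots
#' are the intensity-weighted centroids of above-threshold connected
#' components (labelled with `EBImage::bwlabel`); linking is greedy nearest
#' neighbour with a hard displacement gate, and unlinked spots start new
#' tracks. No gap closing, splitting or merging.
#'
#' @param stack 3-D array from [gen_image_stack()] or a TIFF path.
#' @param threshold Intensity threshold, counts.
#' @param max_disp Linking gate, pixels.
#' @param pixel_size Micrometres per pixel for the output positions.
#' @param frame_interval Seconds per frame for the output table.
#' @return A `track_table` (positions in um). Empty, with a warning, when
#'   no spots are detected.
#' @export
detect_and_link <- function(stack, threshold, max_disp = 5,
                            pixel_size = NULL, frame_interval = NULL) {
  if (is.character(stack)) {
    pages <- tiff::readTIFF(stack, all = TRUE)
    stack <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                              length(pages)))
    for (fi in seq_along(pages)) stack[, , fi] <- pages[[fi]] * 65535
  }
  pixel_size <- pixel_size %||% attr(stack, "pixel_size") %||% 1
  frame_interval <- frame_interval %||% attr(stack, "frame_interval") %||% 1
  n_frames <- dim(stack)[3]
  if (n_frames < 2) {
    rlang::abort("need >= 2 frames to link.", class = "dorsaflow_argument_error")
  }
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    rlang::abort("detect_and_link() requires the EBImage package.",
                 class = "dorsaflow_configuration_error")
  }

  detections <- lapply(seq_len(n_frames), function(fi) {
    img <- stack[, , fi]
    labels <- EBImage::bwlabel(img > threshold)
    n_obj <- max(labels)
    if (n_obj == 0) return(NULL)
    cents <- t(vapply(seq_len(n_obj), function(k) {
      idx <- which(labels == k, arr.ind = TRUE)
      wts <- img[labels == k]
      c(x = sum((idx[, 2] - 0.5) * wts) / sum(wts),
        y = sum((idx[, 1] - 0.5) * wts) / sum(wts))
    }, numeric(2)))
    cents
  })
  if (all(vapply(detections, is.null, logical(1)))) {
    rlang::warn("no spots detected in any frame")
    empty <- tibble::tibble(track_id = integer(), frame = integer(),
                            time = numeric(), x = numeric(), y = numeric())
    return(new_track_table(empty, frame_interval, pixel_size, c(1, 0)))
  }

  # greedy frame-to-frame linking with gate
  next_id <- 0L
  active <- NULL  # tibble: id, x, y (pixel coords at last frame seen)
  rows <- list()
  for (fi in seq_len(n_frames)) {
    det <- detections[[fi]]
    if (is.null(det)) { active <- NULL; next }
    assigned <- rep(NA_integer_, nrow(det))
    if (!is.null(active) && nrow(active) > 0) {
      D <- outer(active$x, det[, "x"], "-")^2 + outer(active$y, det[, "y"], "-")^2
      D <- sqrt(D)
      while (TRUE) {
        m <- which(D == min(D), arr.ind = TRUE)[1, , drop = FALSE]
        if (D[m] > max_disp) break
        assigned[m[2]] <- active$id[m[1]]
        D[m[1], ] <- Inf
        D[, m[2]] <- Inf
        if (all(is.infinite(D))) break
      }
    }
    new_spots <- which(is.na(assigned))
    if (length(new_spots) > 0) {
      assigned[new_spots] <- next_id + seq_along(new_spots)
      next_id <- next_id + length(new_spots)
    }
    rows[[fi]] <- tibble::tibble(
      track_id = assigned, frame = fi - 1L,
      x = unname(det[, "x"]), y = unname(det[, "y"])
    )
    active <- tibble::tibble(id = assigned, x = unname(det[, "x"]),
                             y = unname(det[, "y"]))
  }
  spots <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      time = .data$frame * frame_interval,
      x = .data$x * pixel_size,
      y = .data$y * pixel_size
    )
  track_table(spots, frame_interval, pixel_size = pixel_size)
}
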