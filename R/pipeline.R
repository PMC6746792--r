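#' Default pipeline configuration
#'
#' A single nested list drives every subcommand of [run_dorsaflow()]. All
#' physical quantities are SI internally; flow rates are accepted in ul/min
#' at the boundary and converted where used. Per-mode sections carry the
#' assay protocols (traction: constant 10 ul/min; viscoelasticity: creep
#' window under 600 or 1000 ul/min; rupture: the 200-1400 ul/min step
#' ramp).
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(width = 1e-3, height = 1e-4),
    fluid = list(viscosity = 1e-3, density = 1000),
    particle = list(diameter = 2.8e-6, material_density = 1300),
    interface = list(cortical_viscosity = 550, contact_angle = pi / 2),
    h = 5e-6,
    nu = 0.4,
    seed = 1,
    heights = default_heights(),
    qc = list(min_samples = 5, r2_flag = 0.8, side_wall_min = 200),
    calibrate = list(rates = seq(200, 1400, by = 200)),
    traction = list(flow_rate = 10),
    visco = list(flow_rate = 1000, flow_on = 10, flow_off = 100),
    rupture = list(rates = seq(200, 1400, by = 200), step_duration = 30,
                   lead_in = 60, threshold_um = 5),
    simulate = list(mode = "creep", n = 50, noise_sd = 5e-8)
  ), class = "pipeline_config")
}

#' Read and validate a pipeline configuration file
#'
#' YAML or JSON (by extension); values are merged over [default_config()]
#' so a file need only state what differs from the defaults.
#'
#' @param path Config file path, or `NULL` for the defaults.
#' @return Validated `pipeline_config`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg <- utils::modifyList(cfg, user)
    class(cfg) <- "pipeline_config"
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  positive <- c("geometry.width", "geometry.height", "fluid.viscosity",
                "fluid.density", "particle.diameter",
                "particle.material_density", "interface.cortical_viscosity",
                "h")
  for (field in positive) {
    parts <- strsplit(field, ".", fixed = TRUE)[[1]]
    val <- purrr::reduce(parts, function(acc, p) acc[[p]], .init = cfg)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0) {
      rlang::abort(paste0("config field `", field, "` must be a positive number"),
                   class = "dorsaflow_config_error")
    }
  }
  if (cfg$nu < 0 || cfg$nu > 0.5) {
    rlang::abort("config field `nu` must lie in [0, 0.5]",
                 class = "dorsaflow_config_error")
  }
  if (cfg$h < 3e-6 || cfg$h > 8e-6) {
    rlang::warn("reference height `h` outside the typical 3-8 um cell-height band")
  }
  cfg
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; changes iff the configuration
#' content changes.
#'
#' @param cfg A `pipeline_config`.
#' @return Character scalar (32 hex digits).
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

config_context <- function(cfg) {
  hydro_context(
    geometry = channel_geometry(cfg$geometry$width, cfg$geometry$height),
    fluid = fluid_properties(cfg$fluid$viscosity, cfg$fluid$density),
    particle = particle_properties(cfg$particle$diameter,
                                   cfg$particle$material_density),
    h = cfg$h
  )
}

#' Run a measurement pipeline end to end
#'
#' Orchestrates the five analysis stages over a configuration:
#' \describe{
#'   \item{`calibrate`}{Builds the force-distance calibration for each
#'     configured flow rate; writes `cal_<rate>.json` (logistic parameters
#'     and r-squared) and `cal_<rate>.csv` (samples).}
#'   \item{`traction`}{Reads a track CSV, applies QC, and writes per-track
#'     dorsal traction forces to `traction.csv`.}
#'   \item{`visco`}{Fits the four-element creep model per track; writes
#'     `visco.csv`.}
#'   \item{`rupture`}{Counts attached beads per ramp step and writes the
#'     rupture analysis to `rupture.json`.}
#'   \item{`simulate`}{Generates synthetic tracks for the configured mode;
#'     writes `tracks.csv`, `truth.csv` and `scenario.json`.}
#' }
#' Every run writes `report.json` (package version, subcommand, seed,
#' config hash, QC counts). Identical config and seed reproduce identical
#' numeric outputs.
#'
#' @param subcommand One of `"calibrate"`, `"traction"`, `"visco"`,
#'   `"rupture"`, `"simulate"`.
#' @param config A `pipeline_config` (see [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @param tracks Track CSV path (required for traction/visco/rupture).
#' @param seed Overrides `config$seed`.
#' @return The stage result, invisibly.
#' @export
run_dorsaflow <- function(subcommand = c("calibrate", "traction", "visco",
                                         "rupture", "simulate"),
                          config = default_config(), out_dir = ".",
                          tracks = NULL, seed = NULL) {
  subcommand <- match.arg(subcommand)
  config <- validate_config(config)
  seed <- seed %||% config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- config_context(config)
  qc_counts <- list()

  result <- switch(
    subcommand,
    calibrate = {
      cals <- lapply(config$calibrate$rates, function(r) {
        cal <- build_calibration(r, ctx, heights = config$heights)
        jsonlite::write_json(
          list(flow_rate = r, A1 = cal$A1, A2 = cal$A2, x0 = cal$x0,
               p = cal$p, r2 = cal$r_squared),
          file.path(out_dir, sprintf("cal_%g.json", r)),
          auto_unbox = TRUE, digits = NA
        )
        readr::write_csv(
          dplyr::transmute(cal$samples, x_m = .data$x, F_N = .data$F),
          file.path(out_dir, sprintf("cal_%g.csv", r))
        )
        cal
      })
      names(cals) <- as.character(config$calibrate$rates)
      cals
    },
    simulate = {
      sim <- switch(
        config$simulate$mode,
        traction = gen_traction_tracks(n = config$simulate$n,
                                       noise_sd = config$simulate$noise_sd,
                                       Q = config$traction$flow_rate,
                                       ctx = ctx, seed = seed),
        creep = gen_creep_tracks(n = config$simulate$n,
                                 noise_sd = config$simulate$noise_sd,
                                 flow_on = config$visco$flow_on,
                                 flow_off = config$visco$flow_off,
                                 Q = config$visco$flow_rate,
                                 ctx = ctx, seed = seed),
        ramp = gen_ramp_tracks(n = config$simulate$n,
                               protocol = config_protocol(config),
                               noise_sd = config$simulate$noise_sd,
                               ctx = ctx, seed = seed),
        rlang::abort(paste0("unknown simulate mode: ", config$simulate$mode),
                     class = "dorsaflow_config_error")
      )
      write_tracks_csv(sim$tracks, file.path(out_dir, "tracks.csv"))
      readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))
      jsonlite::write_json(
        list(mode = config$simulate$mode, n = config$simulate$n,
             noise_sd = config$simulate$noise_sd, seed = seed),
        file.path(out_dir, "scenario.json"), auto_unbox = TRUE, digits = NA
      )
      sim
    },
    traction = {
      tab <- load_tracks(tracks, config)
      tab <- apply_side_wall_qc(tab, config)
      qc_counts$tracks_in <- dplyr::n_distinct(tab$track_id)
      if (qc_counts$tracks_in == 0) {
        rlang::abort("QC left zero usable tracks.",
                     class = "dorsaflow_qc_empty_error")
      }
      cal <- build_calibration(config$traction$flow_rate, ctx,
                               heights = config$heights)
      F_A <- applied_force(config$h, cal)
      iface <- interface_model(config$interface$cortical_viscosity,
                               config$interface$contact_angle)
      res <- traction_forces(tab, F_A, iface, ctx$particle)
      qc_counts$flagged <- sum(res$flagged)
      readr::write_csv(
        dplyr::transmute(res, .data$track_id, u_m_per_s = .data$u,
                         F_A_N = .data$F_A, F_D_N = .data$F_D,
                         F_C_N = .data$F_C, r2 = .data$r_squared,
                         flag = .data$flagged),
        file.path(out_dir, "traction.csv")
      )
      res
    },
    visco = {
      tab <- load_tracks(tracks, config)
      tab <- apply_side_wall_qc(tab, config)
      qc_counts$tracks_in <- dplyr::n_distinct(tab$track_id)
      if (qc_counts$tracks_in == 0) {
        rlang::abort("QC left zero usable tracks.",
                     class = "dorsaflow_qc_empty_error")
      }
      cal <- build_calibration(config$visco$flow_rate, ctx,
                               heights = config$heights)
      F_A <- applied_force(config$h, cal)
      fa <- flow_axis(tab)
      fits <- tab |>
        dplyr::group_by(.data$track_id) |>
        dplyr::group_map(function(g, key) {
          fit <- tryCatch({
            cs <- compliance_from_displacement(
              g, config$visco$flow_on, config$visco$flow_off, F_A, ctx,
              flow_axis = fa)
            fit_kv4(cs, nu = config$nu)
          }, error = function(e) NULL)
          if (is.null(fit)) {
            return(tibble::tibble(track_id = key$track_id, G0 = NA_real_,
                                  G1 = NA_real_, mu0p = NA_real_,
                                  mu1p = NA_real_, tau_s = NA_real_,
                                  E0 = NA_real_, E1 = NA_real_,
                                  mu0 = NA_real_, mu1 = NA_real_,
                                  E0_plus_E1 = NA_real_, sse = NA_real_,
                                  r2 = NA_real_))
          }
          tibble::tibble(track_id = key$track_id, G0 = fit$G0, G1 = fit$G1,
                         mu0p = fit$mu0p, mu1p = fit$mu1p, tau_s = fit$tau,
                         E0 = fit$E0, E1 = fit$E1, mu0 = fit$mu0,
                         mu1 = fit$mu1, E0_plus_E1 = fit$E0_plus_E1,
                         sse = fit$sse, r2 = fit$r_squared)
        }) |>
        dplyr::bind_rows()
      qc_counts$fit_failures <- sum(is.na(fits$G0))
      readr::write_csv(fits, file.path(out_dir, "visco.csv"))
      fits
    },
    rupture = {
      tab <- load_tracks(tracks, config)
      protocol <- config_protocol(config)
      cals <- lapply(config$rupture$rates, build_calibration, ctx = ctx,
                     heights = config$heights)
      schedule <- step_force_schedule(protocol, cals, x = config$h)
      counts <- count_attached(tab, protocol,
                               threshold_um = config$rupture$threshold_um)
      res <- rupture_force(counts, schedule$force)
      jsonlite::write_json(
        list(forces_N = schedule$force, counts = counts,
             survival = res$survival, rupture_force_N = res$rupture_force),
        file.path(out_dir, "rupture.json"), auto_unbox = TRUE, digits = NA
      )
      res
    }
  )

  report <- list(
    package = "dorsaflow",
    version = as.character(utils::packageVersion("dorsaflow")),
    subcommand = subcommand,
    seed = seed,
    config_hash = config_hash(config),
    qc = qc_counts,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

config_protocol <- function(cfg) {
  ramp_protocol(cfg$rupture$rates, cfg$rupture$step_duration,
                cfg$rupture$lead_in)
}

load_tracks <- function(tracks, cfg) {
  if (is.null(tracks)) {
    rlang::abort("this subcommand requires a `tracks` CSV path.",
                 class = "dorsaflow_config_error")
  }
  if (!file.exists(tracks)) {
    rlang::abort(paste0("tracks file not found: ", tracks),
                 class = "dorsaflow_config_error")
  }
  read_tracks_csv(tracks)
}

apply_side_wall_qc <- function(tab, cfg) {
  if ("wall_distance" %in% names(tab)) {
    filter_side_wall(tab, cfg$qc$side_wall_min)
  } else {
    tab
  }
}
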