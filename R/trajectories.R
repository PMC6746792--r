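#' Assemble a track table from per-spot records
#'
#' A track table is the package's carrier for single-particle tracking data:
#' a tibble with one row per spot (columns `track_id`, `frame`, `time`, `x`,
#' `y`, optionally `wall_distance`) and acquisition metadata stored as
#' attributes. Positions are in micrometres in image coordinates (origin
#' top-left), times in seconds from acquisition start. The flow direction in
#' image coordinates is carried as a unit 2-vector because it is known from
#' the rig, not inferred from the data.
#'
#' Tracks with fewer than 2 spots carry no kinematic information and are
#' dropped with a message.
#'
#' @param spots Data frame with columns `track_id`, `frame`, `x`, `y` and
#'   optionally `time` (seconds) and `wall_distance` (micrometres, distance
#'   of the track from the nearest channel side wall).
#' @param frame_interval Time between frames, seconds.
#' @param pixel_size Pixel size, micrometres per pixel (metadata only here;
#'   positions in `spots` are already physical).
#' @param flow_axis Unit 2-vector giving the flow direction in image
#'   coordinates. Normalised if not already unit length.
#' @return A `track_table` (tibble subclass) ordered by track and time.
#' @examples
#' spots <- data.frame(track_id = 1, frame = 0:3, x = 0:3, y = 0)
#' tt <- track_table(spots, frame_interval = 0.5)
#' @export
track_table <- function(spots, frame_interval, pixel_size = 1,
                        flow_axis = c(1, 0)) {
  stopifnot(is.data.frame(spots))
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      frame_interval <= 0) {
    rlang::abort("`frame_interval` must be a positive scalar (seconds).",
                 class = "dorsaflow_argument_error")
  }
  if (pixel_size <= 0) {
    rlang::abort("`pixel_size` must be positive (um/pixel).",
                 class = "dorsaflow_argument_error")
  }
  flow_axis <- normalize_flow_axis(flow_axis)

  need <- c("track_id", "frame", "x", "y")
  missing_cols <- setdiff(need, names(spots))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "dorsaflow_format_error"
    )
  }
  spots <- tibble::as_tibble(spots)
  if (!"time" %in% names(spots)) {
    spots$time <- spots$frame * frame_interval
  }
  if (!all(is.finite(spots$x)) || !all(is.finite(spots$y))) {
    rlang::abort("non-finite positions in spot table.",
                 class = "dorsaflow_data_error")
  }

  spots <- dplyr::arrange(spots, .data$track_id, .data$time)
  bad <- spots |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(mono = all(diff(.data$time) > 0), .groups = "drop") |>
    dplyr::filter(!.data$mono)
  if (nrow(bad) > 0) {
    rlang::abort(
      paste0("non-monotone frames within track(s): ",
             paste(bad$track_id, collapse = ", ")),
      class = "dorsaflow_data_error"
    )
  }

  n_spots <- dplyr::count(spots, .data$track_id)
  short <- n_spots$track_id[n_spots$n < 2]
  if (length(short) > 0) {
    message(length(short), " track(s) with < 2 samples dropped")
    spots <- dplyr::filter(spots, !.data$track_id %in% short)
  }

  new_track_table(spots, frame_interval, pixel_size, flow_axis)
}

new_track_table <- function(spots, frame_interval, pixel_size, flow_axis) {
  structure(
    spots,
    class = c("track_table", class(tibble::tibble())),
    frame_interval = frame_interval,
    pixel_size = pixel_size,
    flow_axis = flow_axis
  )
}

normalize_flow_axis <- function(flow_axis) {
  if (length(flow_axis) != 2 || !all(is.finite(flow_axis))) {
    rlang::abort("`flow_axis` must be a finite 2-vector.",
                 class = "dorsaflow_argument_error")
  }
  nrm <- sqrt(sum(flow_axis^2))
  if (nrm == 0) {
    rlang::abort("`flow_axis` must be non-zero.",
                 class = "dorsaflow_argument_error")
  }
  flow_axis / nrm
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf(
    "<track_table> %d tracks, %d spots | frame interval %g s | flow axis (%.3g, %.3g)\n",
    dplyr::n_distinct(x$track_id), nrow(x),
    attr(x, "frame_interval"),
    attr(x, "flow_axis")[1], attr(x, "flow_axis")[2]
  ))
  NextMethod()
}

#' Track-table metadata accessors
#'
#' @param table A `track_table`.
#' @return `flow_axis()` the unit flow-direction vector; `frame_interval()`
#'   the frame spacing in seconds.
#' @export
flow_axis <- function(table) attr(table, "flow_axis") %||% c(1, 0)

#' @rdname flow_axis
#' @export
frame_interval <- function(table) attr(table, "frame_interval")

`%||%` <- function(a, b) if (is.null(a)) b else a

# keep numeric track ids numeric so ordering survives a CSV round trip
maybe_numeric <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) num else x
}

#' Read particle tracks from CSV
#'
#' Two header dialects are recognised: TrackMate spot exports
#' (`TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`, optionally `POSITION_T`)
#' and a generic dialect (`track`, `frame`, `x`, `y`). TrackMate exports
#' sometimes carry extra non-numeric header rows below the column names;
#' those rows are discarded. Positions are multiplied by `pixel_size`, so an
#' export already in physical units passes through with `pixel_size = 1`.
#'
#' @param path CSV file path.
#' @param pixel_size Micrometres per pixel applied to the position columns.
#' @param frame_interval Seconds per frame; used to derive times as
#'   `frame * frame_interval` when the file carries no explicit time column
#'   (`time` or `POSITION_T`), and replaced by the median sampling interval
#'   when it does.
#' @param flow_axis Unit flow-direction vector in image coordinates.
#' @return A [track_table()].
#' @export
read_tracks_csv <- function(path, pixel_size = 1, frame_interval = 1,
                            flow_axis = c(1, 0)) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  nm <- names(raw)
  if ("TRACK_ID" %in% nm) {
    need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
    missing_cols <- setdiff(need, nm)
    if (length(missing_cols) > 0) {
      rlang::abort(paste0("missing required column(s): ",
                          paste(missing_cols, collapse = ", ")),
                   class = "dorsaflow_format_error")
    }
    # TrackMate writes 3 repeated-header/units rows under the column names
    keep <- !is.na(suppressWarnings(as.numeric(raw$FRAME)))
    raw <- raw[keep, ]
    spots <- tibble::tibble(
      track_id = maybe_numeric(raw$TRACK_ID),
      frame = as.numeric(raw$FRAME),
      x = as.numeric(raw$POSITION_X) * pixel_size,
      y = as.numeric(raw$POSITION_Y) * pixel_size
    )
    if ("POSITION_T" %in% nm) spots$time <- as.numeric(raw$POSITION_T)
  } else if (all(c("track", "frame", "x", "y") %in% nm)) {
    spots <- tibble::tibble(
      track_id = maybe_numeric(raw$track),
      frame = as.numeric(raw$frame),
      x = as.numeric(raw$x) * pixel_size,
      y = as.numeric(raw$y) * pixel_size
    )
    if ("time" %in% nm) spots$time <- as.numeric(raw$time)
    if ("wall_distance" %in% nm) {
      spots$wall_distance <- as.numeric(raw$wall_distance)
    }
  } else {
    rlang::abort(
      paste0("unrecognised header; need TrackMate columns ",
             "(TRACK_ID, FRAME, POSITION_X, POSITION_Y) or generic ",
             "(track, frame, x, y); missing required column(s): ",
             paste(setdiff(c("track", "frame", "x", "y"), nm), collapse = ", ")),
      class = "dorsaflow_format_error"
    )
  }
  if ("time" %in% names(spots)) {
    # explicit times override the declared frame interval
    dt <- stats::median(unlist(tapply(spots$time, spots$track_id, diff)),
                        na.rm = TRUE)
    if (is.finite(dt) && dt > 0) frame_interval <- dt
  }
  track_table(spots, frame_interval = frame_interval,
              pixel_size = pixel_size, flow_axis = flow_axis)
}

#' Write a track table as generic-dialect CSV
#'
#' Positions are written in micrometres and times in seconds, so the file
#' round-trips through [read_tracks_csv()] with `pixel_size = 1` without
#' knowing the original frame interval.
#'
#' @param table A `track_table`.
#' @param path Output path.
#' @export
write_tracks_csv <- function(table, path) {
  out <- tibble::tibble(
    track = table$track_id,
    frame = table$frame,
    time = table$time,
    x = table$x,
    y = table$y
  )
  if ("wall_distance" %in% names(table)) out$wall_distance <- table$wall_distance
  readr::write_csv(out, path)
  invisible(path)
}

#' Project a trajectory onto the flow axis
#'
#' Returns the scalar displacement series s(t) = ((x, y)(t) - (x, y)(t0)) .
#' flow_axis for t >= t0, positive along the flow direction. The series is
#' translation invariant by construction: only displacements from the
#' reference time enter.
#'
#' @param traj Single-track data frame with columns `time`, `x`, `y`.
#' @param t0 Reference time (seconds), typically flow onset; must lie within
#'   the track's time span.
#' @param flow_axis Unit flow vector; defaults to the track-table attribute.
#' @return Tibble with columns `time` (s) and `s` (um).
#' @export
project_displacement <- function(traj, t0 = NULL, flow_axis = NULL) {
  traj <- as_single_track(traj)
  flow_axis <- normalize_flow_axis(flow_axis %||% attr(traj, "flow_axis") %||% c(1, 0))
  if (is.null(t0)) t0 <- min(traj$time)
  if (t0 < min(traj$time) || t0 > max(traj$time)) {
    rlang::abort("`t0` outside the track's time span.",
                 class = "dorsaflow_argument_error")
  }
  i0 <- which.min(abs(traj$time - t0))
  keep <- traj$time >= traj$time[i0]
  tibble::tibble(
    time = traj$time[keep],
    s = (traj$x[keep] - traj$x[i0]) * flow_axis[1] +
        (traj$y[keep] - traj$y[i0]) * flow_axis[2]
  )
}

as_single_track <- function(traj) {
  if ("track_id" %in% names(traj) && dplyr::n_distinct(traj$track_id) > 1) {
    rlang::abort("expected a single track; got several track_ids.",
                 class = "dorsaflow_argument_error")
  }
  traj
}

#' Estimate particle speed from a displacement series
#'
#' Ordinary least-squares line through s(t). Cell-bound particles under
#' constant hydrodynamic force move at constant velocity, so the fit's
#' r-squared doubles as a QC statistic: tracks with r-squared below
#' `r2_flag` are flagged (never dropped) so the user can audit them.
#'
#' @param series Tibble from [project_displacement()] (`time` s, `s` um).
#' @param min_samples QC minimum number of samples (default 5).
#' @param r2_flag Flag threshold on the fit r-squared (default 0.8).
#' @return One-row tibble: `speed` (m/s, magnitude), `sign` (+1 along flow,
#'   -1 against), `r_squared`, `flagged`.
#' @export
estimate_velocity <- function(series, min_samples = 5, r2_flag = 0.8) {
  if (nrow(series) < min_samples) {
    rlang::abort(
      sprintf("velocity QC requires >= %d samples; got %d",
              min_samples, nrow(series)),
      class = "dorsaflow_qc_error"
    )
  }
  if (diff(range(series$time)) <= 0) {
    rlang::abort("zero time span in displacement series.",
                 class = "dorsaflow_argument_error")
  }
  fit <- stats::lm(s ~ time, data = series)
  slope_um_s <- unname(stats::coef(fit)[2])
  ss_tot <- sum((series$s - mean(series$s))^2)
  if (ss_tot == 0) {
    # constant series: no motion, r-squared undefined
    return(tibble::tibble(speed = 0, sign = 1, r_squared = NA_real_,
                          flagged = TRUE))
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  tibble::tibble(
    speed = abs(slope_um_s) * 1e-6,
    sign = ifelse(slope_um_s >= 0, 1, -1),
    r_squared = r2,
    flagged = r2 < r2_flag
  )
}

#' Drop tracks near the channel side walls
#'
#' Near the side walls of the rectangular channel the parallel-plate flow
#' profile no longer holds, so only tracks farther than `min_distance` from
#' the nearest side wall are analysed (default 200 um).
#'
#' @param table A `track_table` with a `wall_distance` column (um).
#' @param min_distance Retention threshold, um.
#' @return Filtered `track_table`; logs the number of removed tracks.
#' @export
filter_side_wall <- function(table, min_distance = 200) {
  if (!"wall_distance" %in% names(table)) {
    rlang::abort("`wall_distance` metadata column missing.",
                 class = "dorsaflow_configuration_error")
  }
  ids <- table |>
    dplyr::distinct(.data$track_id, .data$wall_distance) |>
    dplyr::filter(.data$wall_distance > min_distance)
  removed <- dplyr::n_distinct(table$track_id) - nrow(ids)
  if (removed > 0) message(removed, " track(s) removed by side-wall filter")
  out <- dplyr::filter(table, .data$track_id %in% ids$track_id)
  new_track_table(out, attr(table, "frame_interval"),
                  attr(table, "pixel_size"), flow_axis(table))
}
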