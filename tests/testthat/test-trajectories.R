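test_that("generic CSV round-trips through write/read", {
  set.seed(42)
  spots <- purrr::map_dfr(1:50, function(i) {
    n <- sample(5:20, 1)
    tibble::tibble(track_id = i, frame = 0:(n - 1),
                   x = round(runif(n, 0, 600), 6),
                   y = round(runif(n, 0, 600), 6))
  })
  tt <- track_table(spots, frame_interval = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tt, path)
  back <- read_tracks_csv(path, pixel_size = 1, frame_interval = 0.5)
  expect_equal(as.numeric(back$track_id), as.numeric(tt$track_id))
  expect_equal(back$time, tt$time)
  expect_equal(back$x, tt$x, tolerance = 1e-6)
  expect_equal(back$y, tt$y, tolerance = 1e-6)
})

test_that("generic dialect parses with frame-interval timing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track,frame,x,y",
               "1,0,0,0", "1,1,1,0", "1,2,2,0",
               "2,0,5,5", "2,1,5,6", "2,2,5,7"), path)
  tt <- read_tracks_csv(path, frame_interval = 0.5)
  expect_equal(dplyr::n_distinct(tt$track_id), 2)
  expect_equal(unique(tt$time), c(0, 0.5, 1.0))
})

test_that("TrackMate dialect passes physical units through at pixel_size 1", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "LABEL,ID,TRACK_ID,POSITION_X,POSITION_Y,POSITION_T,FRAME",
    "Label,Spot ID,Track ID,X,Y,T,Frame",           # TrackMate extra header
    "label,id,track,(micron),(micron),(sec),",      # rows are discarded
    "ID1,1,0,12.5,30.25,0,0",
    "ID2,2,0,13.5,30.25,1,1",
    "ID3,3,0,14.5,30.25,2,2"
  ), path)
  tt <- read_tracks_csv(path, pixel_size = 1, frame_interval = 1)
  expect_equal(tt$x, c(12.5, 13.5, 14.5))
  expect_equal(tt$y, rep(30.25, 3))
})

test_that("missing columns and non-monotone frames raise classed errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track,frame,x", "1,0,0"), path)
  expect_error(read_tracks_csv(path), class = "dorsaflow_format_error",
               regexp = "y")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track,frame,x,y", "7,1,0,0", "7,1,1,0", "7,0,2,0"), path2)
  expect_error(read_tracks_csv(path2), class = "dorsaflow_data_error",
               regexp = "7")
})

test_that("empty table writes a header-only CSV", {
  tt <- track_table(tibble::tibble(track_id = integer(), frame = integer(),
                                   x = numeric(), y = numeric()),
                    frame_interval = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tt, path)
  expect_equal(readLines(path), "track,frame,time,x,y")
})

test_that("projection recovers along-flow motion and kills orthogonal motion", {
  tr <- straight_track(1, duration = 3, dt = 1, direction = c(1, 0))
  s <- project_displacement(tr, t0 = 0, flow_axis = c(1, 0))
  expect_equal(s$s, c(0, 1, 2, 3))

  perp <- straight_track(1, duration = 3, dt = 1, direction = c(0, 1))
  s_perp <- project_displacement(perp, t0 = 0, flow_axis = c(1, 0))
  expect_equal(s_perp$s, rep(0, 4))

  # 20 nm/s against the flow over 300 s
  slow <- straight_track(0.02, duration = 300, dt = 10, direction = c(-1, 0))
  s_slow <- project_displacement(slow, t0 = 0, flow_axis = c(1, 0))
  expect_equal(s_slow$s[length(s_slow$s)], -6.0)

  expect_error(project_displacement(tr, t0 = 99),
               class = "dorsaflow_argument_error")
})

test_that("projection is translation invariant", {
  set.seed(7)
  tr <- straight_track(0.5, duration = 50, dt = 5, direction = c(-1, 0))
  tr$x <- tr$x + rnorm(nrow(tr), 0, 0.1)
  shifted <- dplyr::mutate(tr, x = x + 123.4, y = y - 55.5)
  expect_equal(project_displacement(tr, 0)$s,
               project_displacement(shifted, 0)$s)
})

test_that("velocity estimation recovers slope, sign and r-squared", {
  tr <- straight_track(0.02, duration = 300, dt = 10, direction = c(1, 0))
  v <- estimate_velocity(project_displacement(tr, 0))
  expect_equal(v$speed, 2e-8, tolerance = 1e-10)
  expect_equal(v$sign, 1)
  expect_equal(v$r_squared, 1, tolerance = 1e-12)
  expect_false(v$flagged)

  # constant series: zero speed, undefined r-squared, flagged
  const <- tibble::tibble(time = seq(0, 100, 10), s = rep(0, 11))
  v0 <- estimate_velocity(const)
  expect_equal(v0$speed, 0)
  expect_true(is.na(v0$r_squared))
  expect_true(v0$flagged)

  expect_error(estimate_velocity(const[1:3, ]), class = "dorsaflow_qc_error")
})

test_that("noisy velocity is recovered within 15% of generator truth", {
  set.seed(11)
  times <- seq(0, 300, by = 10)
  s <- 0.02 * times + rnorm(length(times), 0, 0.05)  # 20 nm/s + 50 nm noise
  v <- estimate_velocity(tibble::tibble(time = times, s = s))
  expect_lt(abs(v$speed - 2e-8) / 2e-8, 0.15)
})

test_that("side-wall filter retains exactly the far-from-wall tracks", {
  set.seed(3)
  wall <- runif(30, 0, 500)
  spots <- purrr::map_dfr(1:30, function(i) {
    tibble::tibble(track_id = i, frame = 0:4, x = 1:5, y = 0,
                   wall_distance = wall[i])
  })
  tt <- track_table(spots, frame_interval = 1)
  kept <- suppressMessages(filter_side_wall(tt, 200))
  expect_equal(dplyr::n_distinct(kept$track_id), sum(wall > 200))
  expect_true(all(kept$wall_distance > 200))

  far <- track_table(dplyr::mutate(spots, wall_distance = 500), 1)
  expect_equal(nrow(filter_side_wall(far, 200)), nrow(far))
  near <- track_table(dplyr::mutate(spots, wall_distance = 100), 1)
  expect_equal(nrow(suppressMessages(filter_side_wall(near, 200))), 0)

  no_meta <- track_table(dplyr::select(spots, -wall_distance), 1)
  expect_error(filter_side_wall(no_meta),
               class = "dorsaflow_configuration_error")
})
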