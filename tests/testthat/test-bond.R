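test_that("ramp protocol defaults reproduce the step-wise assay", {
  p <- ramp_protocol()
  expect_equal(p$rate, seq(200, 1400, 200))
  expect_equal(nrow(p), 7)
  expect_equal(attr(p, "total_duration"), 270)
  expect_equal(p$t_end - p$t_start, rep(30, 7))
  expect_error(ramp_protocol(c(200, 200, 400)),
               class = "dorsaflow_argument_error")
})

test_that("force schedule is monotone and anchored at ~320/~640 pN", {
  p <- ramp_protocol()
  cals <- lapply(p$rate, build_calibration, ctx = default_ctx)
  sched <- step_force_schedule(p, cals, x = 5e-6)
  expect_true(all(diff(sched$force) > 0))
  expect_equal(sched$force[1] * 1e12, 320, tolerance = 0.1)
  expect_equal(sched$force[2] * 1e12, 640, tolerance = 0.1)

  single <- step_force_schedule(ramp_protocol(200), cals[1], x = 5e-6)
  expect_equal(nrow(single), 1)
  expect_error(step_force_schedule(p, cals[1:3]),
               class = "dorsaflow_configuration_error")
})

test_that("attachment counting follows track persistence and displacement", {
  p <- ramp_protocol()
  # persistent sub-threshold tracks: constant counts
  times <- seq(0, 270, 1)
  quiet <- purrr::map_dfr(1:5, function(i) {
    tibble::tibble(track_id = i, frame = seq_along(times) - 1, time = times,
                   x = 100 + i, y = 100)
  })
  tt <- track_table(quiet, frame_interval = 1)
  expect_equal(count_attached(tt, p), rep(5L, 8))

  # one track ends mid-step-3: drops out of counts from step 4 on
  cut <- dplyr::filter(quiet, track_id != 1 | time < p$t_start[3] + 10)
  counts <- count_attached(track_table(cut, frame_interval = 1), p)
  expect_equal(counts, c(5L, 5L, 5L, 4L, 4L, 4L, 4L, 4L))

  # one track sweeps 10 um downstream during step 2
  moved <- dplyr::mutate(quiet, x = x + ifelse(
    track_id == 2 & time >= p$t_start[2] + 5, 10, 0))
  counts2 <- count_attached(track_table(moved, frame_interval = 1), p)
  expect_equal(counts2, c(5L, 5L, 4L, 4L, 4L, 4L, 4L, 4L))

  expect_error(count_attached(track_table(quiet[0, ], 1), p),
               class = "dorsaflow_data_error")
})

test_that("rupture force picks the largest fractional survivor loss", {
  forces <- c(320, 640, 960, 1280, 1600, 1920, 2240) * 1e-12
  # sharp first-step drop
  res1 <- rupture_force(c(50, 10, 8, 8, 8, 8, 8), forces)
  expect_equal(res1$rupture_step, 1)
  expect_equal(res1$rupture_force, forces[1])
  expect_equal(res1$survival[1], 1)

  # second-step drop: 27% of the step-1 survivors disengage at ~640 pN
  res2 <- rupture_force(c(50, 45, 33, 33, 33, 33, 33), forces)
  expect_equal(res2$rupture_step, 2)
  expect_equal(res2$rupture_force, forces[2])
  expect_equal(res2$detached_fraction[2], (45 - 33) / 45)
  expect_equal(res2$detached_fraction[2], 0.267, tolerance = 1e-2)

  # no detachment: flagged, rupture undefined
  res3 <- rupture_force(rep(40, 7), forces)
  expect_true(res3$flagged)
  expect_true(is.na(res3$rupture_force))

  # ties resolve to the earliest step
  res4 <- rupture_force(c(40, 20, 10, 10, 10, 10, 10), forces)
  expect_equal(res4$rupture_step, 1)

  expect_error(rupture_force(c(0, 0, 0), forces[1:3]),
               class = "dorsaflow_data_error")
  expect_error(rupture_force(c(10, 12, 12), forces[1:3]),
               class = "dorsaflow_data_error")
})

test_that("point-mass thresholds reproduce brute-force first exceedance", {
  p <- ramp_protocol()
  forces <- vapply(p$rate, dorsaflow:::terminal_drag, numeric(1),
                   ctx = default_ctx)
  # thresholds between every pair of adjacent step forces
  grid <- c(0.5 * forces[1],
            (forces[-length(forces)] + forces[-1]) / 2)
  for (Ti in grid) {
    sim <- gen_ramp_tracks(n = 20, protocol = p, forces = forces,
                           thresholds = rep(Ti, 20), mixture = "manual",
                           seed = 77)
    counts <- count_attached(sim$tracks, p)
    res <- rupture_force(counts, forces)
    expected_step <- which(forces > Ti)[1]  # brute-force first exceedance
    expect_equal(res$rupture_step, expected_step)
    expect_equal(counts, ifelse(seq_len(8) <= expected_step, 20L, 0L))
  }
})

test_that("generator bookkeeping: counts equal truth-table counts exactly", {
  sim <- gen_ramp_tracks(n = 60, seed = 13)
  p <- ramp_protocol()
  counts <- count_attached(sim$tracks, p)
  truth_counts <- vapply(1:8, function(k) {
    sum(sim$truth$detach_step_true >= k)
  }, numeric(1))
  expect_equal(as.numeric(counts), truth_counts)
})

test_that("integrin-like mixture: ~27% detach at step 2, then a plateau", {
  sim <- gen_ramp_tracks(n = 50, mixture = "integrin", seed = 19)
  p <- ramp_protocol()
  counts <- count_attached(sim$tracks, p)
  res <- rupture_force(counts, sim$forces)
  expect_equal(res$rupture_step, 2)
  expect_equal(res$detached_fraction[2], 0.27, tolerance = 0.1)
  # plateau: no further detachment above the rupture step
  expect_equal(res$survival[3], res$survival[8])
  expect_gt(res$survival[7], 0)
})

test_that("degenerate mixtures hit the survival endpoints", {
  p <- ramp_protocol()
  forces <- vapply(p$rate, dorsaflow:::terminal_drag, numeric(1),
                   ctx = default_ctx)
  all_weak <- gen_ramp_tracks(n = 10, forces = forces, mixture = "manual",
                              thresholds = rep(0.9 * forces[1], 10),
                              seed = 3)
  counts_w <- count_attached(all_weak$tracks, p)
  expect_equal(as.numeric(counts_w / counts_w[1]), c(1, rep(0, 7)))

  all_strong <- gen_ramp_tracks(n = 10, forces = forces, mixture = "manual",
                                thresholds = rep(10 * forces[7], 10),
                                seed = 3)
  counts_s <- count_attached(all_strong$tracks, p)
  expect_equal(as.numeric(counts_s / counts_s[1]), rep(1, 8))
})
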