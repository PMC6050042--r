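test_that("segmentation finds well-separated blobs and filters by area", {
  st <- make_blob_stack(peaks = c(100, 90, 80),
                        centers = list(c(12, 12), c(40, 15), c(25, 45)))
  fr <- segment_frame(st, 1, min_area = 5, max_area = 2000)
  expect_equal(nrow(fr$rois), 3)
  # centroids near construction (0-based coordinates)
  got <- fr$rois[order(fr$rois$x), c("x", "y")]
  expect_equal(got$x, c(12, 25, 40), tolerance = 0.1)
  # area filter removes a small blob
  fr2 <- segment_frame(st, 1, min_area = 500, max_area = 2000)
  expect_equal(nrow(fr2$rois), 0)
  # mean * area = integrated intensity, within 1e-6 relative
  expect_equal(fr$rois$mean_reporter * fr$rois$area, fr$rois$total_reporter,
               tolerance = 1e-6)
})

test_that("blank frames give empty ROI sets, missing channels an error", {
  blank <- time_lapse_stack(
    list(morphology = array(5, dim = c(32, 32, 1))), timestamps_h = 24)
  fr <- segment_frame(blank, 1)
  expect_equal(nrow(fr$rois), 0)
  expect_error(segment_frame(blank, 1, channel = "gfp"), "channel")
  expect_error(segment_frame(blank, 1, min_area = 10, max_area = 5))
})

test_that("ROIs within a frame are disjoint and labels unique", {
  cfg <- sim_config(n_cells = 20, field_size = c(256, 256), seed = 31)
  sim <- simulate_timelapse(cfg)
  fr <- segment_frame(sim$stack, 1)
  expect_equal(anyDuplicated(fr$rois$label), 0L)
  # label image partitions the above-threshold support: per-label counts
  # match the feature table areas
  counts <- tabulate(fr$labels[fr$labels > 0])
  expect_equal(sort(counts[counts > 0]), sort(fr$rois$area))
})

test_that("stationary and slowly moving cells yield unbroken tracks", {
  st <- make_blob_stack(n_frames = 10)
  rois <- segment_stack(st, min_area = 5)
  tracks <- track_cells(st, rois)
  expect_length(tracks, 2)
  expect_true(all(vapply(tracks, function(tr) nrow(tr$obs), 1L) == 10))
  # one cell drifting 2 px/frame stays a single track
  size <- 64
  arr <- array(0, dim = c(size, size, 8))
  for (f in 1:8) {
    m <- matrix(0, size, size)
    arr[, , f] <- lfmkit:::add_gaussian_blob(m, 15 + 2 * f, 20, 3, 3, 0, 100)
  }
  st2 <- time_lapse_stack(list(morphology = arr), timestamps_h = 24 * (1:8))
  tracks2 <- track_cells(st2, segment_stack(st2, min_area = 5),
                         max_displacement = 10)
  expect_length(tracks2, 1)
  expect_equal(nrow(tracks2[[1]]$obs), 8)
  expect_error(track_cells(st2, list()), "every frame")
})

test_that("death calling applies the intensity floor rule at the right frame", {
  means <- c(100, 98, 97, 96, 10, 9, 8, 7, 6, 5)
  tr <- make_track(1, "g", "unclassified", 10, means = means)
  out <- call_death(tr, fluorescence_floor = 0.25)
  expect_equal(out$status, "dead")
  expect_equal(out$death_time, 5)       # frame 5 = 120 h = day 5
  expect_true(is.na(out$censor_time))
  # no ROI retained after death
  expect_true(all(out$obs$time_h <= out$death_time * 24))
})

test_that("stable tracks are censored at last observation", {
  tr <- make_track(1, "g", "unclassified", 10)
  out <- call_death(tr)
  expect_equal(out$status, "alive-at-end")
  expect_equal(out$censor_time, 10)
  expect_true(is.na(out$death_time))
})

test_that("a vanished track is a death; rounding plus decline is a death", {
  # vanishes after frame 6, away from the border
  tr <- make_track(1, "g", "unclassified", 6)
  out <- call_death(tr)
  expect_equal(out$status, "dead")
  expect_equal(out$death_time, 7)       # first missing frame
  # eccentricity collapse with declining intensity
  tr2 <- make_track(1, "g", "unclassified", 10,
                    means = c(100, 100, 60, 50, 40, 30, 20, 18, 17, 16))
  tr2$obs$eccentricity <- c(0.8, 0.8, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  out2 <- call_death(tr2, fluorescence_floor = 0.1)
  expect_equal(out2$status, "dead")
  expect_equal(out2$death_time, 3)
  # a track ending at the field edge is lost, not dead
  tr3 <- make_track(1, "g", "unclassified", 6)
  tr3$obs$x <- 1; tr3$obs$y <- 10
  out3 <- call_death(tr3, edge_margin = 5)
  expect_equal(out3$status, "lost")
  expect_equal(out3$censor_time, 6)
})

test_that("track status conserves the cohort and deaths are monotone", {
  cfg <- sim_config(n_cells = 30, baseline_hazard = 0.15, seed = 33)
  sim <- simulate_timelapse(cfg)
  tracks <- lapply(track_cells(sim$stack, segment_stack(sim$stack)),
                   call_death)
  status <- vapply(tracks, `[[`, "", "status")
  expect_true(all(status %in% c("dead", "alive-at-end", "lost")))
  # every track has exactly one exit time, so alive / dead-by / exited-by
  # partition the cohort at every day
  exit_time <- vapply(tracks, function(tr)
    if (identical(tr$status, "dead")) tr$death_time else tr$censor_time, 1)
  expect_true(all(is.finite(exit_time)))
  nf <- length(sim$truth$timestamps_h)
  for (f in c(3, 6, nf)) {
    day <- sim$truth$timestamps_h[f] / 24
    is_dead <- vapply(tracks, function(tr)
      identical(tr$status, "dead"), TRUE)
    alive <- sum(exit_time > day)
    dead_by <- sum(is_dead & exit_time <= day)
    gone_by <- sum(!is_dead & exit_time <= day)
    expect_equal(alive + dead_by + gone_by, length(tracks))
  }
  # dead tracks carry no observation after the death time
  for (tr in tracks[status == "dead"])
    expect_true(all(tr$obs$time_h / 24 <= tr$death_time))
})

test_that("time series extraction mirrors the track observations", {
  tr <- make_track(1, "g", "dead", 4)
  ts <- extract_timeseries(tr, "reporter")
  expect_equal(nrow(ts), nrow(tr$obs))
  expect_equal(ts$mean, rep(200, 4))
  expect_error(extract_timeseries(tr, "tritc"), "channel")
})

test_that("registration recovers constructed shifts", {
  base <- matrix(0, 64, 64)
  base <- lfmkit:::add_gaussian_blob(base, 30, 25, 5, 5, 0, 100)
  base <- lfmkit:::add_gaussian_blob(base, 45, 40, 4, 4, 0, 80)
  # zero drift -> identity
  st0 <- time_lapse_stack(list(ch = array(rep(base, 3), c(64, 64, 3))),
                          timestamps_h = 1:3)
  r0 <- register_stack(st0)
  expect_equal(r0$transforms$dx, c(0, 0, 0), tolerance = 1e-6)
  # integer shift (3, 5) px recovered as (-3, -5)
  sh <- pmax(lfmkit:::apply_shift(base, 5, 3), 0)
  st1 <- time_lapse_stack(list(ch = array(c(base, sh), c(64, 64, 2))),
                          timestamps_h = 1:2)
  r1 <- register_stack(st1)
  expect_equal(r1$transforms$dx[2], -3, tolerance = 1e-6)
  expect_equal(r1$transforms$dy[2], -5, tolerance = 1e-6)
  expect_lt(max(abs(r1$stack$channels$ch[, , 2] - base)), 1e-6)
  # subpixel shift 1.5 px recovered within 0.25 px
  sh2 <- pmax(lfmkit:::apply_shift(base, 1.5, -1.5), 0)
  st2 <- time_lapse_stack(list(ch = array(c(base, sh2), c(64, 64, 2))),
                          timestamps_h = 1:2)
  r2 <- register_stack(st2)
  expect_lt(abs(r2$transforms$dy[2] + 1.5), 0.25)
  expect_lt(abs(r2$transforms$dx[2] - 1.5), 0.25)
  # featureless frame: warning + identity
  stf <- time_lapse_stack(list(ch = array(c(base, matrix(0, 64, 64)),
                                          c(64, 64, 2))), timestamps_h = 1:2)
  expect_warning(rf <- register_stack(stf), "featureless")
  expect_equal(rf$transforms$dx[2], 0)
  expect_error(register_stack(time_lapse_stack(
    list(ch = array(base, c(64, 64, 1))), timestamps_h = 1)), "2 frames")
})
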