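# Dropout labeling, fast-phase detection, patching, arrests, and the
# partition/idempotence properties of the segmentation stage.

test_that("dropout labeling covers truth intervals and degenerate cases", {
  # all-valid trace: no dropout intervals
  rec <- simulate_sinusoidal_record(spec_okr_roll(20), quiet_truth(seed = 1))
  lab <- find_dropouts(to_angles(rec))
  expect_equal(nrow(label_intervals(lab, "dropout")), 0)

  # simulated dropouts are covered >= 99%
  drops <- data.frame(start = c(4, 11.2, 15), end = c(5, 11.6, 15.3))
  rec2 <- simulate_sinusoidal_record(
    spec_okr_roll(20), sim_truth(gain = 0.5, dropout_intervals = drops, seed = 2))
  trc2 <- to_angles(rec2)
  lab2 <- find_dropouts(trc2)
  tm <- rec2$samples$t >= 4 & rec2$samples$t < 5 |
    rec2$samples$t >= 11.2 & rec2$samples$t < 11.6 |
    rec2$samples$t >= 15 & rec2$samples$t < 15.3
  expect_gte(sum(lab2$class[tm] == "dropout") / sum(tm), 0.99)

  # fully invalid trace: one interval spanning the record (no calibration
  # error path taken, so build the labels directly)
  trc3 <- trc2
  trc3$samples$valid <- FALSE
  trc3$samples$h <- NA_real_
  trc3$samples$v <- NA_real_
  lab3 <- find_dropouts(trc3)
  iv <- label_intervals(lab3, "dropout")
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 0)
  expect_equal(iv$end, 20, tolerance = 0.01)
})

test_that("fast-phase detection matches ground truth with low false-positive rate", {
  # saccade-free record: zero fast phases
  rec0 <- simulate_sinusoidal_record(spec_okr_roll(20), quiet_truth(seed = 1))
  lab0 <- detect_fast_phases(to_angles(rec0))
  expect_equal(nrow(label_intervals(lab0, "fast_phase")), 0)

  hits <- fps <- numeric(0)
  for (seed in c(7, 17, 27)) {
    rec <- simulate_sinusoidal_record(spec_okr_roll(),
                                      sim_truth(gain = 0.5, seed = seed))
    lab <- detect_fast_phases(to_angles(rec))
    det <- attr(lab, "fast_phases")
    tt <- rec$truth$fast_phase_times
    matched <- vapply(tt, function(x) {
      any(det$start - 0.02 <= x & det$end + 0.02 >= x)
    }, logical(1))
    false_det <- vapply(seq_len(nrow(det)), function(j) {
      !any(tt >= det$start[j] - 0.02 & tt <= det$end[j] + 0.02)
    }, logical(1))
    hits <- c(hits, mean(matched))
    fps <- c(fps, mean(false_det))
  }
  expect_gte(min(hits), 0.95)
  expect_lt(max(fps), 0.05)
})

test_that("a threshold below the expected slow-phase peak is a configuration error", {
  rec <- simulate_sinusoidal_record(spec_vvor(20), quiet_truth(seed = 1))
  expect_error(detect_fast_phases(to_angles(rec),
                                  detector_config(velocity_threshold = 20)),
               "below the expected peak")
})

test_that("patching is the identity on saccade-free records and never touches slow samples", {
  rec <- simulate_sinusoidal_record(spec_okr_roll(20),
                                    sim_truth(gain = 0.5, fast_phase_rate = 0,
                                              seed = 3))
  trc <- segment_record(rec)
  expect_equal(trc$samples$vv, trc$samples$vv_raw)

  rec2 <- simulate_sinusoidal_record(spec_okr_roll(20),
                                     sim_truth(gain = 0.5, seed = 3))
  trc2 <- segment_record(rec2)
  slow <- trc2$labels$class == "slow"
  expect_equal(trc2$samples$vv[slow], trc2$samples$vv_raw[slow])
  expect_gt(sum(!slow), 0)
})

test_that("patching a single fast phase restores the saccade-free Fourier gain", {
  spec <- spec_okr_roll(20)
  clean <- simulate_sinusoidal_record(spec, quiet_truth(gain = 0.5, seed = 4))
  g_clean <- analyze_sinusoidal_record(clean)$gain
  one <- simulate_sinusoidal_record(
    spec, sim_truth(gain = 0.5, noise_sd = 0, fast_phase_rate = 0,
                    fast_phase_times = 9.3, seed = 4))
  g_one <- analyze_sinusoidal_record(one)$gain
  expect_lt(abs(g_one - g_clean), 0.01)
})

test_that("intervals touching the record edge are excluded, not extrapolated", {
  rec <- simulate_sinusoidal_record(
    spec_okr_roll(20),
    sim_truth(gain = 0.5, noise_sd = 0, fast_phase_rate = 0,
              dropout_intervals = data.frame(start = 0.2, end = 0.5),
              fast_phase_times = 0.35, seed = 5))
  # the fast phase sits inside a dropout: no slow anchor before it
  trc <- segment_record(rec)
  early <- trc$labels$class[trc$samples$t < 0.6]
  expect_true(all(early %in% c("dropout", "deleted_artifact", "slow")))
  expect_false(any(early == "fast_phase"))
})

test_that("labels partition the record: every sample has exactly one class", {
  rec <- simulate_step_record(
    spec_steps(c(10, -10, 20)),
    sim_truth(gain = 0.4, dropout_rate = 0.05,
              arrest_intervals = data.frame(start = 5, end = 6.5), seed = 6))
  trc <- segment_record(rec)
  expect_true(all(trc$labels$class %in%
    c("slow", "fast_phase", "glissade_excluded", "arrest", "dropout",
      "deleted_artifact")))
  expect_equal(length(trc$labels$class), nrow(trc$samples))
})

test_that("arrest spans are recovered and no fast phases are labeled inside them", {
  arr <- data.frame(start = c(5.0, 20.3), end = c(6.8, 21.9))
  rec <- simulate_step_record(
    spec_steps(c(10, -10, 20, -20)),
    sim_truth(gain = 0.4, arrest_intervals = arr, seed = 3))
  trc <- segment_record(rec)
  t <- trc$samples$t
  tm <- (t >= 5 & t < 6.8) | (t >= 20.3 & t < 21.9)
  cover <- sum(trc$labels$class[tm] == "arrest") / sum(tm)
  expect_gte(cover, 0.9)

  # arrests-only record (no fast phases generated): none labeled inside
  rec2 <- simulate_step_record(
    spec_steps(c(10, -10, 20, -20)),
    sim_truth(gain = 0.4, arrest_intervals = arr, fast_phase_rate = 0,
              seed = 3), reset_threshold = Inf)
  trc2 <- segment_record(rec2)
  tm2 <- (trc2$samples$t >= 5 & trc2$samples$t < 6.8) |
    (trc2$samples$t >= 20.3 & trc2$samples$t < 21.9)
  expect_false(any(trc2$labels$class[tm2] == "fast_phase"))
})

test_that("residual glissades bias step gain by less than 0.02 at the default exclusion", {
  errs <- vapply(1:6, function(seed) {
    tr <- sim_truth(gain = 0.4, glissade_tau = 0.05, seed = seed)
    st <- analyze_step_record(simulate_step_record(spec_steps(c(10, -10)), tr))
    mean(abs(st$gain - 0.4))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})
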