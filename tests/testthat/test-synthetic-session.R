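# Synthetic oculography-session generator: determinism, conservation,
# ground-truth consistency, and the closed-form identity cases.

test_that("a unit-gain compensatory response exactly negates the table velocity", {
  spec <- spec_vvor(20)
  rec <- simulate_sinusoidal_record(spec, quiet_truth(gain = 1, seed = 1))
  t <- rec$samples$t
  vel_amp <- 4.8 * 2 * pi * 0.8
  # slow-phase eye velocity equals the negated table velocity (compensatory)
  table_vel <- -vel_amp * cos(2 * pi * 0.8 * t) # d/dt of the table channel
  expect_equal(rec$truth$slow_velocity, -table_vel, tolerance = 1e-12)
  # and the table channel itself is the negative of the drive integral
  expect_equal(rec$samples$table_position, -4.8 * sin(2 * pi * 0.8 * t),
               tolerance = 1e-12)
})

test_that("identical (spec, truth, seed) give bit-identical records", {
  spec <- spec_okr_roll(20)
  tr <- sim_truth(gain = 0.5, seed = 7)
  r1 <- simulate_sinusoidal_record(spec, tr)
  r2 <- simulate_sinusoidal_record(spec, tr)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$truth$fast_phase_times, r2$truth$fast_phase_times)
  r3 <- simulate_sinusoidal_record(spec, sim_truth(gain = 0.5, seed = 8))
  expect_false(identical(r1$samples$pupil_v, r3$samples$pupil_v))

  s1 <- simulate_step_record(spec_steps(c(10, -10)), tr)
  s2 <- simulate_step_record(spec_steps(c(10, -10)), tr)
  expect_identical(s1$samples, s2$samples)
})

test_that("eye position is the integral of the generated velocity", {
  # noise-free, saccade-free: the calibrated angle must equal resting plus
  # the cumulative integral of the true slow-phase velocity
  spec <- spec_okr_roll(20)
  rec <- simulate_sinusoidal_record(spec, quiet_truth(gain = 0.7, seed = 3))
  trc <- to_angles(rec)
  dt <- 1 / rec$sample_rate
  expected <- rec$truth$resting_v +
    c(0, cumsum(rec$truth$slow_velocity[-length(rec$truth$slow_velocity)])) * dt
  expect_lt(max(abs(trc$samples$v - expected)), 1e-6)
})

test_that("every labeled truth interval lies inside the record and is disjoint within class", {
  spec <- spec_okr_roll()
  for (seed in c(2, 11, 23)) {
    rec <- simulate_sinusoidal_record(
      spec, sim_truth(gain = 0.6, dropout_rate = 0.05, seed = seed))
    dur <- spec$record_duration
    for (nm in c("fast_phase_intervals", "glissade_intervals",
                 "dropout_intervals")) {
      iv <- rec$truth[[nm]]
      if (is.null(iv) || nrow(iv) == 0) next
      expect_true(all(iv$start >= 0 & iv$end <= dur + 1e-9), label = nm)
      if (nrow(iv) > 1) {
        iv <- iv[order(iv$start), ]
        expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)] - 1e-9), label = nm)
      }
    }
  }
})

test_that("a single constant-velocity step yields the closed-form mean eye velocity", {
  rec <- simulate_step_record(spec_steps(c(10)), quiet_truth(gain = 0.3, seed = 1))
  sched <- rec$truth$step_schedule
  in_step <- rec$samples$t >= sched$t_on[1] & rec$samples$t < sched$t_off[1]
  expect_equal(mean(rec$truth$slow_velocity[in_step]), 3.0, tolerance = 1e-9)
})

test_that("behavioral arrests decelerate the eye and suppress fast phases", {
  arr <- data.frame(start = 5, end = 7)
  rec <- simulate_step_record(
    spec_steps(c(10, -10)),
    sim_truth(gain = 0.4, arrest_intervals = arr, noise_sd = 0, seed = 4))
  t <- rec$samples$t
  late_arrest <- t >= 6.5 & t < 7
  expect_lt(max(abs(rec$truth$slow_velocity[late_arrest])), 0.01)
  fp <- rec$truth$fast_phase_times
  expect_false(any(fp >= 5 & fp < 7))
})

test_that("dropouts blank the pupil channels but not the stimulus channels", {
  drops <- data.frame(start = c(3, 10), end = c(4, 10.5))
  rec <- simulate_sinusoidal_record(
    spec_okr_roll(20), sim_truth(gain = 0.5, dropout_intervals = drops, seed = 6))
  m <- rec$samples$t >= 3 & rec$samples$t < 4
  expect_true(all(is.na(rec$samples$pupil_v[m])))
  expect_true(all(is.na(rec$samples$pupil_h[m])))
  expect_true(all(is.finite(rec$samples$planetarium_velocity[m])))
})

test_that("the calibration sweep follows rp * sin(angle) and rejects degenerate input", {
  sw <- simulate_calibration_sweep(1.0, c(-10, 0, 10), noise_sd = 0)
  expect_equal(sw$pupil_displacement, c(-0.17365, 0, 0.17365),
               tolerance = 1e-4)
  expect_error(simulate_calibration_sweep(1.0, c(5, 5)), "distinct")
  expect_error(simulate_calibration_sweep(1.0, numeric(0)), "empty")
})

test_that("generator rejects invalid sampling and reset parameters", {
  expect_error(simulate_sinusoidal_record(spec_vvor(), sim_truth(), sample_rate = -1),
               "sample_rate")
  expect_error(simulate_sinusoidal_record(spec_vvor(), sim_truth(),
                                          reset_threshold = 0),
               "threshold")
  expect_error(stimulus_spec("yaw", "sinusoid", "table", frequency = 0,
                             amplitude = 4), "frequency")
  expect_error(stimulus_spec("roll", "velocity_steps", "planetarium",
                             speeds = c(0, 10)), "nonzero")
})

test_that("the 120 Hz video quantization stage holds values between frames", {
  rec <- simulate_sinusoidal_record(spec_okr_roll(10), quiet_truth(seed = 2),
                                    video_rate = 120)
  # at 500 samples/s a 120 Hz hold repeats each value for >= 4 samples
  reps <- rle(rec$samples$pupil_v)$lengths
  expect_gte(min(reps[-length(reps)]), 4)
})
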