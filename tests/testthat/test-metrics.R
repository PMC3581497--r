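# Response measures: cycle averaging, Fourier gain/phase, hemicycle
# regression, step gains and tuning curves, resting position, velocity bias,
# and their invariance properties.

test_that("cycle averaging reproduces a clean cycle and enforces the cycle minimum", {
  rec <- simulate_sinusoidal_record(spec_okr_roll(20), quiet_truth(gain = 0.5, seed = 1))
  trc <- segment_record(rec)
  avg <- average_cycles(trc)
  expect_equal(avg$n_cycles, 8L)
  va <- 4 * 2 * pi * 0.4
  expect_equal(avg$stimulus, va * cos(2 * pi * avg$phase), tolerance = 0.01)
  expect_equal(avg$response, 0.5 * va * cos(2 * pi * avg$phase),
               tolerance = 0.01)
  # 5 s = 2 complete cycles < minimum 3
  rec2 <- simulate_sinusoidal_record(spec_okr_roll(5), quiet_truth(seed = 1))
  expect_error(average_cycles(segment_record(rec2)),
               "insufficient clean cycles")
})

test_that("Fourier gain and phase match closed forms", {
  # identity: response == stimulus
  theta <- (seq_len(100) - 0.5) / 100
  va <- 10
  avg <- structure(list(phase = theta,
                        response = va * sin(2 * pi * theta),
                        stimulus = va * sin(2 * pi * theta),
                        n = rep(10L, 100), n_cycles = 10L, frequency = 0.4),
                   class = "cycle_average")
  gp <- fourier_gain_phase(avg)
  expect_equal(gp$gain, 1, tolerance = 1e-10)
  expect_equal(gp$phase, 0, tolerance = 1e-8)

  # half-amplitude response delayed by 45 degrees
  avg2 <- avg
  avg2$response <- 0.5 * va * sin(2 * pi * theta - pi / 4)
  gp2 <- fourier_gain_phase(avg2)
  expect_equal(gp2$gain, 0.5, tolerance = 1e-10)
  expect_equal(gp2$phase, -45, tolerance = 1e-8)

  # zero stimulus is an undefined gain
  avg3 <- avg
  avg3$stimulus <- rep(0, 100)
  expect_error(fourier_gain_phase(avg3), "undefined")
})

test_that("simulator gain and phase are recovered within tolerance", {
  rec <- simulate_sinusoidal_record(spec_okr_roll(),
                                    sim_truth(gain = 0.62, phase = 10, seed = 11))
  res <- analyze_sinusoidal_record(rec)
  expect_lt(abs(res$gain - 0.62), 0.02)
  expect_lt(abs(res$phase - 10), 2)
})

test_that("hemicycle gains recover symmetric and asymmetric truth", {
  spec <- spec_okr_roll()
  # symmetric: both hemicycles at 0.4, and equal to the full-cycle gain
  recs <- lapply(c(41, 42, 43), function(s) {
    simulate_sinusoidal_record(spec, sim_truth(gain = 0.4, phase = 0, seed = s))
  })
  res <- lapply(recs, analyze_sinusoidal_record, hemicycles = TRUE)
  expect_lt(abs(mean(vapply(res, `[[`, 1, "gain_up")) - 0.4), 0.02)
  expect_lt(abs(mean(vapply(res, `[[`, 1, "gain_down")) - 0.4), 0.02)

  # asymmetric 0.5 up / 0.3 down (seed 9 and neighbors)
  hr <- vapply(c(9, 19, 29), function(s) {
    rec <- simulate_sinusoidal_record(
      spec, sim_truth(gain_up = 0.5, gain_down = 0.3, phase = 0, seed = s))
    r <- analyze_sinusoidal_record(rec, hemicycles = TRUE)
    c(r$gain_up, r$gain_down)
  }, numeric(2))
  expect_lt(abs(mean(hr[1, ]) - 0.5), 0.03)
  expect_lt(abs(mean(hr[2, ]) - 0.3), 0.03)
})

test_that("hemicycle and full-cycle gains agree exactly on a pure noiseless sine", {
  rec <- simulate_sinusoidal_record(spec_okr_roll(20), quiet_truth(gain = 0.45, seed = 2))
  trc <- segment_record(rec)
  hc <- hemicycle_gains(trc)
  gp <- fourier_gain_phase(average_cycles(trc))
  expect_equal(hc$gain_up, hc$gain_down, tolerance = 1e-4)
  expect_equal(hc$gain_up, gp$gain, tolerance = 1e-3)
})

test_that("step gain handles the stationary-eye and recovery cases", {
  # eye stationary: the velocity-ratio arithmetic gives gain 0 (the arrest
  # classifier is bypassed here -- a fully stationary eye would otherwise be
  # excluded as one long behavioral arrest)
  rec0 <- simulate_step_record(spec_steps(c(10)), quiet_truth(gain = 0, seed = 1))
  trc0 <- to_angles(rec0)
  trc0 <- patch_intervals(trc0, detect_fast_phases(trc0))
  g0 <- step_gain(trc0, rec0$truth$step_schedule[1, ])
  expect_equal(g0$gain, 0, tolerance = 1e-9)
  expect_true(g0$usable)

  # truth 0.3 at -20 deg/s with fast phases, seed 2
  rec <- simulate_step_record(spec_steps(c(-20)), sim_truth(gain = 0.3, seed = 2))
  st <- analyze_step_record(rec)
  expect_lt(abs(st$gain - 0.3), 0.02)
})

test_that("speed tuning recovers a declining gain curve from repeated records", {
  gcurve <- tuning_truth_table()
  traces <- lapply(1:4, function(r) {
    segment_record(simulate_step_record(spec_steps(),
                                        sim_truth(gain = gcurve, seed = 3000 + r)))
  })
  st <- speed_tuning(traces)
  m <- merge(st, stats::setNames(gcurve, c("speed", "gtrue")))
  expect_equal(nrow(m), 10)
  expect_lt(max(abs(m$gain - m$gtrue)), 0.03)
})

test_that("delta curves align on speed and handle missing speeds", {
  pre <- structure(data.frame(speed = c(-10, 10, 40), gain = c(0.4, 0.42, 0.2),
                              n = 4L), class = c("speed_tuning", "data.frame"))
  post <- structure(data.frame(speed = c(-10, 10), gain = c(0.35, 0.40),
                               n = 4L), class = c("speed_tuning", "data.frame"))
  expect_equal(delta_curve(pre, pre)$delta, c(0, 0, 0))
  expect_warning(d <- delta_curve(post, pre), "intersection")
  expect_equal(d$speed, c(-10, 10))
  expect_equal(d$delta, c(-0.05, -0.02))
})

test_that("resting position excludes transient eccentric holds and falls back for drift", {
  # constant position
  trc <- to_angles(simulate_stationary_record(
    20, quiet_truth(resting_h = 2, resting_v = 15, seed = 2)))
  rp <- resting_position(trc)
  expect_equal(rp$h, 2, tolerance = 1e-9)
  expect_equal(rp$v, 15, tolerance = 1e-9)

  # one 1-s eccentric excursion then return; resting vertical 18
  exc <- data.frame(onset = 8, duration = 1, amplitude = 6)
  rec <- simulate_stationary_record(
    20, sim_truth(resting_v = 18, fast_phase_rate = 0, seed = 3),
    excursions = exc)
  rp2 <- resting_position(to_angles(rec))
  expect_lt(abs(rp2$v - 18), 0.1)

  # pure linear drift 10 -> 14: whole-record mean 12
  recd <- simulate_stationary_record(
    20, sim_truth(resting_v = 10, drift_bias = 0.2, fast_phase_rate = 0,
                  noise_sd = 0.1, seed = 4))
  rp3 <- resting_position(to_angles(recd))
  expect_lt(abs(rp3$v - 12), 0.1)
})

test_that("mean velocity bias recovers the DC drift and equals the regression C", {
  b0 <- vapply(1:8, function(s) {
    rec <- simulate_sinusoidal_record(spec_okr_roll(),
                                      sim_truth(gain = 0.5, drift_bias = 0, seed = s))
    analyze_sinusoidal_record(rec)$mean_velocity
  }, numeric(1))
  expect_lt(abs(mean(b0)), 0.02)

  b29 <- vapply(1:8, function(s) {
    rec <- simulate_sinusoidal_record(
      spec_okr_roll(), sim_truth(gain = 0.5, drift_bias = 0.29, seed = 30 + s))
    analyze_sinusoidal_record(rec)$mean_velocity
  }, numeric(1))
  expect_lt(abs(mean(b29) - 0.29), 0.02)

  # definitional consistency with the sinusoidal-regression constant
  rec <- simulate_sinusoidal_record(spec_okr_roll(20),
                                    quiet_truth(gain = 0.5, drift_bias = 0.2, seed = 1))
  trc <- segment_record(rec)
  mv <- mean_velocity_bias(trc)
  expect_equal(mv$bias, mv$C)
  expect_equal(mv$bias, 0.2, tolerance = 0.01)
})

test_that("gain is linear in response amplitude and invariant to stimulus start phase", {
  spec <- spec_okr_roll(20)
  g1 <- analyze_sinusoidal_record(
    simulate_sinusoidal_record(spec, quiet_truth(gain = 0.3, seed = 1)))$gain
  g2 <- analyze_sinusoidal_record(
    simulate_sinusoidal_record(spec, quiet_truth(gain = 0.6, seed = 1)))$gain
  expect_equal(g2 / g1, 2, tolerance = 1e-3)

  # shifting the analysis start leaves gain unchanged
  rec <- simulate_sinusoidal_record(spec_okr_roll(30), quiet_truth(gain = 0.5, seed = 2))
  shift <- 625 # a quarter period
  rec2 <- rec
  rec2$samples <- rec$samples[(shift + 1):nrow(rec$samples), ]
  rec2$samples$t <- rec2$samples$t - rec2$samples$t[1]
  rec2$spec$record_duration <- 30 - shift / 500
  ga <- analyze_sinusoidal_record(rec)$gain
  gb <- analyze_sinusoidal_record(rec2)$gain
  expect_lt(abs(ga - gb), 0.005)
})

test_that("superimposed drift changes step gain by drift/speed and sinusoidal gain by < 0.005", {
  spec <- spec_steps()
  base <- sim_truth(gain = 0.34, drift_bias = 0, fast_phase_rate = 0, seed = 11)
  drift <- sim_truth(gain = 0.34, drift_bias = 0.2, fast_phase_rate = 0, seed = 11)
  s0 <- analyze_step_record(simulate_step_record(spec, base, reset_threshold = Inf))
  s1 <- analyze_step_record(simulate_step_record(spec, drift, reset_threshold = Inf))
  d <- merge(s0, s1, by = "speed")
  expect_lt(max(abs((d$gain.y - d$gain.x) - 0.2 / d$speed)), 0.005)
  # at +2.5 deg/s the exact change is 0.08 (not the rounded 0.1)
  expect_equal(d$gain.y[d$speed == 2.5] - d$gain.x[d$speed == 2.5], 0.08,
               tolerance = 0.005)

  sin0 <- analyze_sinusoidal_record(simulate_sinusoidal_record(
    spec_okr_roll(20), quiet_truth(gain = 0.5, seed = 3)))$gain
  sin1 <- analyze_sinusoidal_record(simulate_sinusoidal_record(
    spec_okr_roll(20), quiet_truth(gain = 0.5, drift_bias = 0.2, seed = 3)))$gain
  expect_lt(abs(sin1 - sin0), 0.005)
})
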