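## Synthetic oculography-session generator.
##
## Records are generated in the angle domain (slow-phase velocity -> position,
## fast phases and glissades inserted as displacement waveforms), then
## forward-projected through the same spherical camera geometry the
## calibration module inverts, so round-trip tests exercise the full chain.

## Insert resetting fast phases into a position trace. Returns the correction
## waveform (added to the slow-phase position) plus realized event tables.
## Fast phases are triggered when eccentricity exceeds `reset_threshold` and
## at explicitly scheduled times; none are generated inside arrests.
insert_fast_phases <- function(pos, t, fs, scheduled_times = numeric(0),
                               reset_threshold = 8, overshoot = 0.2,
                               duration = 0.02, glissade_fraction = 0.15,
                               glissade_tau = 0.05, min_amplitude = 1.5,
                               slow_velocity = NULL, arrest_mask = NULL) {
  if (is.na(reset_threshold) || reset_threshold <= 0) {
    stop("reset threshold must be positive")
  }
  n <- length(pos)
  if (is.null(arrest_mask)) arrest_mask <- logical(n)
  if (is.null(slow_velocity)) slow_velocity <- c(diff(pos), 0) * fs
  corr <- numeric(n)
  dur_n <- max(2L, round(duration * fs))
  onsets <- numeric(0)
  amplitudes <- numeric(0)
  sched <- sort(scheduled_times)
  sched <- sched[sched > t[2] & sched < t[n] - duration - 3 * glissade_tau]
  i <- 2L
  last <- n - dur_n - 2L
  repeat {
    if (i > last) break
    cur <- pos[i:last] + corr[i:last]
    thr_idx <- NA_integer_
    hit <- which(abs(cur) > reset_threshold & !arrest_mask[i:last])
    if (length(hit)) thr_idx <- i + hit[1L] - 1L
    sch_idx <- NA_integer_
    sched <- sched[sched >= t[i]]
    while (length(sched)) {
      j <- round(sched[1L] * fs) + 1L
      if (j > last) { sched <- numeric(0); break }
      if (arrest_mask[j]) { sched <- sched[-1L]; next }
      sch_idx <- j
      break
    }
    cand <- c(thr_idx, sch_idx)
    if (all(is.na(cand))) break
    e <- min(cand, na.rm = TRUE)
    x0 <- pos[e] + corr[e]
    if (!is.na(thr_idx) && e == thr_idx) {
      D <- -(1 + overshoot) * x0
    } else {
      dir <- if (slow_velocity[e] >= 0) -1 else 1
      D <- -(1 + overshoot) * x0 + dir * min_amplitude
      ## fast phases have a minimum size; a sub-threshold reset is not made
      if (abs(D) < min_amplitude) D <- sign(D + dir * 1e-9) * min_amplitude
    }
    Dp <- D * (1 + glissade_fraction)
    Dg <- -glissade_fraction * D
    k <- 0:dur_n
    corr[e + k] <- corr[e + k] + Dp * (1 - cos(pi * k / dur_n)) / 2
    tail_idx <- (e + dur_n + 1L):n
    dt_tail <- t[tail_idx] - t[e + dur_n]
    corr[tail_idx] <- corr[tail_idx] + Dp + Dg * (1 - exp(-dt_tail / glissade_tau))
    onsets <- c(onsets, t[e])
    amplitudes <- c(amplitudes, D)
    i <- e + dur_n + 2L
  }
  end_of_record <- t[n] + (t[2] - t[1])
  fp <- merge_intervals(data.frame(
    start = onsets, end = pmin(onsets + duration, end_of_record)))
  gl <- merge_intervals(data.frame(
    start = pmin(onsets + duration, end_of_record),
    end = pmin(onsets + duration + 3 * glissade_tau, end_of_record)))
  if (is.null(fp)) fp <- data.frame(start = numeric(0), end = numeric(0))
  if (is.null(gl)) gl <- data.frame(start = numeric(0), end = numeric(0))
  list(correction = corr,
       fast_phase_times = onsets,
       fast_phase_amplitudes = amplitudes,
       fast_phase_intervals = fp,
       glissade_intervals = gl)
}

## Draw random dropout intervals (Poisson starts, exponential durations).
draw_dropouts <- function(rate, mean_duration, duration) {
  if (rate <= 0) return(data.frame(start = numeric(0), end = numeric(0)))
  k <- stats::rpois(1, rate * duration)
  if (k == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  s <- sort(stats::runif(k, 0, duration))
  d <- stats::rexp(k, 1 / mean_duration)
  merge_intervals(data.frame(start = s, end = pmin(s + d, duration)))
}

## Forward spherical projection of angular eye position to camera units:
## the inverse of to_angles(). Vertical is expressed re: earth-horizontal;
## the camera measures in the head frame, pitched `pitch_offset` deg
## nose-down.
project_to_camera <- function(h, v, rp, reference, pitch_offset) {
  v_cam <- deg2rad(v - pitch_offset)
  list(pupil_v = reference[["v"]] + rp * sin(v_cam),
       pupil_h = reference[["h"]] + rp * cos(v_cam) * sin(deg2rad(h)))
}

## Shared back half of the record generators: noise, optional video-frame
## quantization, projection, dropout blanking, assembly.
assemble_record <- function(t, h_true, v_true, sample_rate, spec, truth,
                            realized, table_position, planetarium_velocity,
                            rp, reference, pitch_offset, video_rate) {
  n <- length(t)
  h <- h_true + stats::rnorm(n, 0, truth$noise_sd)
  v <- v_true + stats::rnorm(n, 0, truth$noise_sd)
  diam <- 3 + stats::rnorm(n, 0, 0.01)
  if (!is.null(video_rate)) {
    frame_idx <- pmin(n, floor(floor(t * video_rate) / video_rate *
                                 sample_rate) + 1L)
    h <- h[frame_idx]
    v <- v[frame_idx]
    diam <- diam[frame_idx]
  }
  cam <- project_to_camera(h, v, rp, reference, pitch_offset)
  dropouts <- realized$dropout_intervals
  if (!is.null(dropouts) && nrow(dropouts)) {
    m <- intervals_to_mask(dropouts, t)
    cam$pupil_h[m] <- NA_real_
    cam$pupil_v[m] <- NA_real_
    diam[m] <- NA_real_
  }
  samples <- data.frame(t = t,
                        pupil_h = cam$pupil_h, pupil_v = cam$pupil_v,
                        cr_h = 0, cr_v = 0,
                        pupil_diameter = diam,
                        table_position = table_position,
                        planetarium_velocity = planetarium_velocity)
  truth_out <- truth
  truth_out[names(realized)] <- realized
  structure(list(samples = samples, sample_rate = sample_rate, spec = spec,
                 truth = truth_out,
                 calibration = list(rp = rp, reference = reference,
                                    pitch_offset = pitch_offset)),
            class = "oculo_record")
}

common_sim_checks <- function(sample_rate, reset_threshold) {
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive")
  }
  ## Inf disables eccentricity-triggered resets; NA/non-positive is an error
  if (is.na(reset_threshold) || reset_threshold <= 0) {
    stop("reset threshold must be positive")
  }
}

#' Simulate a sinusoidal vestibular or optokinetic record
#'
#' Generates one raw multichannel oculography record for a sinusoidal
#' stimulus. The slow-phase eye velocity equals the truth gain times the
#' stimulus velocity (compensatory sign convention: for table rotation the
#' eye moves opposite the table; for planetarium rotation the eye follows
#' the surround), shifted by the truth phase, plus the constant drift bias.
#' Resetting fast phases, post-saccadic glissades, dropouts and position
#' noise are layered on top, and the realized ground truth is embedded in
#' the returned record.
#'
#' @param spec a [stimulus_spec()] with `mode = "sinusoid"`.
#' @param truth a [sim_truth()].
#' @param sample_rate acquisition rate, samples/s (default 500).
#' @param rp true pupil-to-rotation-center distance, camera units.
#' @param reference named camera-unit reference position `c(h =, v =)`.
#' @param pitch_offset head-mount pitch, degrees nose-down (default 20).
#' @param reset_threshold eccentricity (deg) triggering a resetting fast
#'   phase.
#' @param fast_phase_duration saccade duration, s.
#' @param overshoot fraction by which a reset carries the eye past center.
#' @param glissade_fraction fraction of each saccade taken back by the
#'   post-saccadic glissade.
#' @param min_saccade_amplitude amplitude floor (deg) for scheduled fast
#'   phases.
#' @param video_rate optional video frame rate (Hz) for a sample-and-hold
#'   quantization stage before the acquisition clock; `NULL` disables it.
#' @return an `oculo_record`: `$samples` (one row per sample: `t`,
#'   `pupil_h`, `pupil_v`, `cr_h`, `cr_v`, `pupil_diameter`,
#'   `table_position`, `planetarium_velocity`), `$sample_rate`, `$spec`,
#'   `$truth` (with realized event intervals and the true slow-phase
#'   velocity), `$calibration`.
#' @examples
#' spec <- stimulus_spec("yaw", "sinusoid", "table",
#'                       frequency = 0.8, amplitude = 4.8)
#' rec <- simulate_sinusoidal_record(spec, sim_truth(gain = 0.6, seed = 2))
#' @export
simulate_sinusoidal_record <- function(spec, truth = sim_truth(),
                                       sample_rate = 500, rp = 1,
                                       reference = c(h = 0, v = 0),
                                       pitch_offset = 20,
                                       reset_threshold = 8,
                                       fast_phase_duration = 0.02,
                                       overshoot = 0.2,
                                       glissade_fraction = 0.15,
                                       min_saccade_amplitude = 1.5,
                                       video_rate = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(truth, "sim_truth"))
  if (spec$mode != "sinusoid") stop("spec must describe a sinusoidal stimulus")
  common_sim_checks(sample_rate, reset_threshold)
  set.seed(truth$seed)
  dt <- 1 / sample_rate
  n <- round(spec$record_duration * sample_rate)
  t <- (0:(n - 1)) * dt
  omega <- 2 * pi * spec$frequency
  vel_amp <- spec$amplitude * omega
  phi <- deg2rad(truth$phase)
  stim_vel <- vel_amp * cos(omega * t)          # stimulus velocity, deg/s
  drive <- vel_amp * cos(omega * t + phi)       # phase-advanced for the eye
  gain_sel <- truth_gain_at(truth, stim_vel)
  slow_v <- gain_sel * drive + truth$drift_bias # response-channel velocity
  rest <- if (spec$axis == "yaw") truth$resting_h else truth$resting_v
  pos <- rest + c(0, cumsum(slow_v[-n])) * dt

  fp_times <- truth$fast_phase_times
  if (is.null(fp_times) && truth$fast_phase_rate > 0) {
    k <- stats::rpois(1, truth$fast_phase_rate * spec$record_duration)
    fp_times <- sort(stats::runif(k, 0, spec$record_duration))
  }
  fp <- insert_fast_phases(pos - rest, t, sample_rate,
                           scheduled_times = fp_times %||% numeric(0),
                           reset_threshold = reset_threshold,
                           overshoot = overshoot,
                           duration = fast_phase_duration,
                           glissade_fraction = glissade_fraction,
                           glissade_tau = truth$glissade_tau,
                           min_amplitude = min_saccade_amplitude,
                           slow_velocity = slow_v)
  pos <- pos + fp$correction

  dropouts <- truth$dropout_intervals
  if (is.null(dropouts)) {
    dropouts <- draw_dropouts(truth$dropout_rate, truth$dropout_duration,
                              spec$record_duration)
  }

  if (spec$axis == "yaw") {
    h_true <- pos
    v_true <- rep(truth$resting_v, n)
  } else {
    h_true <- rep(truth$resting_h, n)
    v_true <- pos
  }
  ## compensatory convention: the drive the eye follows (`stim_vel`) is the
  ## negated table velocity for vestibular stimuli, and the planetarium
  ## velocity itself for optokinetic stimuli
  table_position <- if (spec$stimulator == "table") {
    -spec$amplitude * sin(omega * t)
  } else rep(0, n)
  planetarium_velocity <- if (spec$stimulator == "planetarium") {
    stim_vel
  } else rep(0, n)

  realized <- list(fast_phase_times = fp$fast_phase_times,
                   fast_phase_intervals = fp$fast_phase_intervals,
                   fast_phase_amplitudes = fp$fast_phase_amplitudes,
                   glissade_intervals = fp$glissade_intervals,
                   dropout_intervals = dropouts,
                   slow_velocity = slow_v,
                   stimulus_velocity = stim_vel)
  assemble_record(t, h_true, v_true, sample_rate, spec, truth, realized,
                  table_position, planetarium_velocity,
                  rp, reference, pitch_offset, video_rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a constant-velocity optokinetic step record
#'
#' Alternating-direction constant-velocity planetarium steps separated by
#' dark gaps. Within each step the slow-phase eye velocity is
#' `gain(speed) * speed + drift_bias`; during dark gaps the optokinetic
#' drive is absent and only the drift remains. Behavioral arrests replace
#' the slow phase with an exponential deceleration to a held eccentric
#' position and suppress fast phases.
#'
#' @inheritParams simulate_sinusoidal_record
#' @param spec a [stimulus_spec()] with `mode = "velocity_steps"`.
#' @param arrest_tau exponential deceleration time constant of a behavioral
#'   arrest, s.
#' @return an `oculo_record`; see [simulate_sinusoidal_record()].
#' @examples
#' spec <- stimulus_spec("roll", "velocity_steps", "planetarium",
#'                       speeds = c(10, -10))
#' rec <- simulate_step_record(spec, sim_truth(gain = 0.3, seed = 3))
#' @export
simulate_step_record <- function(spec, truth = sim_truth(),
                                 sample_rate = 500, rp = 1,
                                 reference = c(h = 0, v = 0),
                                 pitch_offset = 20,
                                 reset_threshold = 8,
                                 fast_phase_duration = 0.02,
                                 overshoot = 0.2,
                                 glissade_fraction = 0.15,
                                 min_saccade_amplitude = 1.5,
                                 arrest_tau = 0.15,
                                 video_rate = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(truth, "sim_truth"))
  if (spec$mode != "velocity_steps") {
    stop("spec must describe a velocity_steps stimulus")
  }
  common_sim_checks(sample_rate, reset_threshold)
  set.seed(truth$seed)
  dt <- 1 / sample_rate
  n <- round(spec$record_duration * sample_rate)
  t <- (0:(n - 1)) * dt
  sched <- step_schedule(spec)
  plan_vel <- rep(0, n)
  slow_v <- rep(truth$drift_bias, n)
  for (i in seq_len(nrow(sched))) {
    in_step <- t >= sched$t_on[i] & t < sched$t_off[i]
    plan_vel[in_step] <- sched$speed[i]
    g <- truth_gain_at(truth, sched$speed[i], speed = sched$speed[i])
    slow_v[in_step] <- g * sched$speed[i] + truth$drift_bias
  }

  arrests <- truth$arrest_intervals
  arrest_mask <- logical(n)
  if (!is.null(arrests) && nrow(arrests)) {
    for (i in seq_len(nrow(arrests))) {
      idx <- which(t >= arrests$start[i] & t < arrests$end[i])
      if (!length(idx)) next
      slow_v[idx] <- slow_v[idx[1]] * exp(-(t[idx] - t[idx[1]]) / arrest_tau)
      arrest_mask[idx] <- TRUE
    }
  }

  rest <- if (spec$axis == "yaw") truth$resting_h else truth$resting_v
  pos <- rest + c(0, cumsum(slow_v[-n])) * dt

  fp_times <- truth$fast_phase_times
  if (is.null(fp_times) && truth$fast_phase_rate > 0) {
    k <- stats::rpois(1, truth$fast_phase_rate * spec$record_duration)
    fp_times <- sort(stats::runif(k, 0, spec$record_duration))
  }
  fp <- insert_fast_phases(pos - rest, t, sample_rate,
                           scheduled_times = fp_times %||% numeric(0),
                           reset_threshold = reset_threshold,
                           overshoot = overshoot,
                           duration = fast_phase_duration,
                           glissade_fraction = glissade_fraction,
                           glissade_tau = truth$glissade_tau,
                           min_amplitude = min_saccade_amplitude,
                           slow_velocity = slow_v,
                           arrest_mask = arrest_mask)
  pos <- pos + fp$correction

  dropouts <- truth$dropout_intervals
  if (is.null(dropouts)) {
    dropouts <- draw_dropouts(truth$dropout_rate, truth$dropout_duration,
                              spec$record_duration)
  }
  if (spec$axis == "yaw") {
    h_true <- pos
    v_true <- rep(truth$resting_v, n)
  } else {
    h_true <- rep(truth$resting_h, n)
    v_true <- pos
  }
  realized <- list(fast_phase_times = fp$fast_phase_times,
                   fast_phase_intervals = fp$fast_phase_intervals,
                   fast_phase_amplitudes = fp$fast_phase_amplitudes,
                   glissade_intervals = fp$glissade_intervals,
                   arrest_intervals = arrests %||%
                     data.frame(start = numeric(0), end = numeric(0)),
                   dropout_intervals = dropouts,
                   slow_velocity = slow_v,
                   step_schedule = sched)
  assemble_record(t, h_true, v_true, sample_rate, spec, truth, realized,
                  rep(0, n), plan_vel, rp, reference, pitch_offset,
                  video_rate)
}

#' Simulate a stationary record in the light (resting-position determination)
#'
#' No rotational stimulus: the eye rests at the truth resting position, with
#' optional drift, noise and transient eccentric excursions (a saccade away,
#' a hold, and a return by saccade or exponential drift), as used to measure
#' resting eye position.
#'
#' @inheritParams simulate_sinusoidal_record
#' @param duration record length, s.
#' @param excursions optional `data.frame(onset, duration, amplitude)` of
#'   transient eccentric excursions on the vertical channel (degrees);
#'   `return_mode` selects how the eye comes back.
#' @param return_mode `"saccade"` or `"drift"` (exponential, time constant
#'   0.3 s).
#' @return an `oculo_record` whose `$spec$mode` is `"stationary"`; the truth
#'   carries `excursion_intervals` for recovery tests.
#' @export
simulate_stationary_record <- function(duration = 20, truth = sim_truth(),
                                       excursions = NULL,
                                       return_mode = c("saccade", "drift"),
                                       sample_rate = 500, rp = 1,
                                       reference = c(h = 0, v = 0),
                                       pitch_offset = 20,
                                       video_rate = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  return_mode <- match.arg(return_mode)
  common_sim_checks(sample_rate, 8)
  set.seed(truth$seed)
  dt <- 1 / sample_rate
  n <- round(duration * sample_rate)
  t <- (0:(n - 1)) * dt
  v_true <- truth$resting_v + truth$drift_bias * t
  h_true <- rep(truth$resting_h, n)
  exc_iv <- data.frame(start = numeric(0), end = numeric(0))
  if (!is.null(excursions) && nrow(excursions)) {
    sac_n <- max(2L, round(0.02 * sample_rate))
    for (i in seq_len(nrow(excursions))) {
      on <- excursions$onset[i]
      dur <- excursions$duration[i]
      amp <- excursions$amplitude[i]
      i0 <- round(on * sample_rate) + 1L
      i1 <- min(n, i0 + sac_n)
      k <- seq_len(i1 - i0 + 1L) - 1L
      wave <- numeric(n)
      wave[i0:i1] <- amp * (1 - cos(pi * k / (i1 - i0))) / 2
      if (i1 < n) wave[(i1 + 1L):n] <- amp
      ret0 <- min(n, round((on + dur) * sample_rate) + 1L)
      if (return_mode == "saccade") {
        ret1 <- min(n, ret0 + sac_n)
        kk <- seq_len(ret1 - ret0 + 1L) - 1L
        wave[ret0:ret1] <- wave[ret0:ret1] -
          amp * (1 - cos(pi * kk / (ret1 - ret0))) / 2
        if (ret1 < n) wave[(ret1 + 1L):n] <- 0
        end_t <- t[ret1]
      } else {
        tail_idx <- ret0:n
        wave[tail_idx] <- amp * exp(-(t[tail_idx] - t[ret0]) / 0.3)
        end_t <- t[ret0] + 3 * 0.3
      }
      v_true <- v_true + wave
      exc_iv <- rbind(exc_iv, data.frame(start = on, end = min(end_t, t[n])))
    }
  }
  dropouts <- truth$dropout_intervals
  if (is.null(dropouts)) {
    dropouts <- draw_dropouts(truth$dropout_rate, truth$dropout_duration,
                              duration)
  }
  spec <- structure(list(axis = "roll", mode = "stationary",
                         stimulator = "planetarium", frequency = NULL,
                         amplitude = NULL, speeds = NULL,
                         step_duration = 1, gap_duration = 1,
                         record_duration = duration, lighting = "light"),
                    class = "stimulus_spec")
  realized <- list(dropout_intervals = dropouts,
                   excursion_intervals = exc_iv,
                   fast_phase_intervals = exc_iv,
                   slow_velocity = rep(truth$drift_bias, n))
  assemble_record(t, h_true, v_true, sample_rate, spec, truth, realized,
                  rep(0, n), rep(0, n), rp, reference, pitch_offset,
                  video_rate)
}

#' Simulate a camera-yaw calibration sweep
#'
#' The oculography camera is yawed about a vertical axis through the
#' recorded eye; the apparent pupil displacement follows
#' `rp_true * sin(camera angle)`, which [estimate_rp()] inverts.
#'
#' @param rp_true true pupil-to-rotation-center distance (camera units).
#' @param angles camera yaw angles, degrees (at least two distinct).
#' @param noise_sd additive displacement noise SD (camera units).
#' @param n_per_angle repeated measurements per angle.
#' @param seed integer seed.
#' @return `data.frame(camera_angle, pupil_displacement)`.
#' @examples
#' simulate_calibration_sweep(1, c(-10, 0, 10))
#' @export
simulate_calibration_sweep <- function(rp_true = 1,
                                       angles = seq(-10, 10, by = 2.5),
                                       noise_sd = 0, n_per_angle = 1,
                                       seed = 1L) {
  if (length(angles) == 0) stop("angle list is empty")
  if (length(unique(angles)) < 2) {
    stop("need at least two distinct camera angles")
  }
  if (!is.finite(rp_true) || rp_true <= 0) stop("rp_true must be positive")
  set.seed(as.integer(seed))
  a <- rep(angles, each = n_per_angle)
  data.frame(camera_angle = a,
             pupil_displacement = rp_true * sin(deg2rad(a)) +
               stats::rnorm(length(a), 0, noise_sd))
}

#' @export
print.oculo_record <- function(x, ...) {
  s <- x$spec
  what <- if (s$mode == "sinusoid") {
    sprintf("%s %s sinusoid %.2g Hz +/-%.3g deg", s$axis, s$stimulator,
            s$frequency, s$amplitude)
  } else if (s$mode == "velocity_steps") {
    sprintf("%s optokinetic steps (%d steps)", s$axis, length(s$speeds))
  } else {
    "stationary (resting position)"
  }
  cat(sprintf("<oculo_record> %s; %gs at %g samples/s (%d samples)%s\n",
              what, s$record_duration, x$sample_rate, nrow(x$samples),
              if (!is.null(x$truth)) "; ground truth embedded" else ""))
  invisible(x)
}

#' @export
plot.oculo_record <- function(x, ...) {
  tr <- to_angles(x)
  resp <- if (x$spec$axis == "yaw") tr$samples$h else tr$samples$v
  graphics::plot(tr$samples$t, resp, type = "l", xlab = "time (s)",
                 ylab = sprintf("%s eye position (deg)", x$spec$axis), ...)
  invisible(x)
}
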