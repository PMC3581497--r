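#' Describe a rotational or optokinetic stimulus
#'
#' A stimulus specification covers the two presentation modes used in murine
#' compensatory eye-movement testing: sinusoidal rotation (of the turntable or
#' the planetarium star pattern) and trains of constant-velocity optokinetic
#' steps of alternating direction separated by dark gaps.
#'
#' @param axis `"yaw"` (horizontal eye movement) or `"roll"` (vertical eye
#'   movement with respect to the recorded eye).
#' @param mode `"sinusoid"` or `"velocity_steps"`.
#' @param stimulator `"table"` (vestibular; the animal rotates) or
#'   `"planetarium"` (optokinetic; the visual surround rotates). Determines
#'   which raw channel carries the stimulus and the compensatory sign
#'   convention.
#' @param frequency sinusoid frequency in Hz.
#' @param amplitude sinusoid position amplitude in degrees (half peak-to-peak).
#' @param speeds signed constant speeds in deg/s for `velocity_steps`; the
#'   default interleaves upward and downward presentations over
#'   2.5-40 deg/s.
#' @param step_duration duration of each constant-velocity period (s).
#' @param gap_duration dark gap between steps (s), during which the
#'   planetarium reverses and re-accelerates.
#' @param record_duration total record length (s). For step records the
#'   default is derived from the step schedule.
#' @param lighting `"light"` or `"dark"`. Rotation in the light with a
#'   stationary lit surround is the vision-enhanced condition.
#' @return an object of class `stimulus_spec`.
#' @examples
#' stimulus_spec("yaw", "sinusoid", "table", frequency = 0.8, amplitude = 4.8)
#' stimulus_spec("roll", "velocity_steps", "planetarium")
#' @export
stimulus_spec <- function(axis = c("yaw", "roll"),
                          mode = c("sinusoid", "velocity_steps"),
                          stimulator = c("table", "planetarium"),
                          frequency = NULL, amplitude = NULL,
                          speeds = NULL,
                          step_duration = 4, gap_duration = 3.5,
                          record_duration = NULL,
                          lighting = c("light", "dark")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  stimulator <- match.arg(stimulator)
  lighting <- match.arg(lighting)
  if (mode == "sinusoid") {
    if (is.null(frequency) || is.null(amplitude) ||
        !is.finite(frequency) || !is.finite(amplitude) ||
        frequency <= 0 || amplitude <= 0) {
      stop("sinusoidal stimuli need frequency > 0 and amplitude > 0")
    }
    if (is.null(record_duration)) record_duration <- 40
  } else {
    if (is.null(speeds)) {
      mags <- c(2.5, 5, 10, 20, 40)
      speeds <- as.vector(rbind(mags, -mags))
    }
    if (length(speeds) == 0 || any(!is.finite(speeds)) || any(speeds == 0)) {
      stop("velocity_steps stimuli need a non-empty vector of nonzero speeds")
    }
    if (stimulator != "planetarium") {
      stop("velocity_steps stimuli are optokinetic (stimulator = 'planetarium')")
    }
    if (is.null(record_duration)) {
      record_duration <- gap_duration +
        length(speeds) * (step_duration + gap_duration)
    }
  }
  if (step_duration <= 0 || gap_duration <= 0 || record_duration <= 0) {
    stop("durations must be positive")
  }
  structure(list(axis = axis, mode = mode, stimulator = stimulator,
                 frequency = frequency, amplitude = amplitude,
                 speeds = speeds, step_duration = step_duration,
                 gap_duration = gap_duration,
                 record_duration = record_duration, lighting = lighting),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  if (x$mode == "sinusoid") {
    cat(sprintf("<stimulus_spec> %s %s sinusoid %.2g Hz +/-%.3g deg, %s, %gs\n",
                x$axis, x$stimulator, x$frequency, x$amplitude, x$lighting,
                x$record_duration))
  } else {
    cat(sprintf(
      "<stimulus_spec> %s optokinetic steps {%s} deg/s (%gs on / %gs dark), %gs\n",
      x$axis, paste(x$speeds, collapse = ", "), x$step_duration,
      x$gap_duration, x$record_duration))
  }
  invisible(x)
}

## Step schedule: alternating constant-velocity periods separated by dark
## gaps, starting and ending with a gap.
step_schedule <- function(spec) {
  stopifnot(spec$mode == "velocity_steps")
  on <- spec$gap_duration +
    (seq_along(spec$speeds) - 1L) * (spec$step_duration + spec$gap_duration)
  data.frame(speed = spec$speeds, t_on = on, t_off = on + spec$step_duration)
}

## Expected peak slow-phase speed for a stimulus, used to sanity-check
## fast-phase detection thresholds (assumes gain <= 1).
peak_slow_speed <- function(spec) {
  if (spec$mode == "sinusoid") {
    2 * pi * spec$frequency * spec$amplitude
  } else {
    max(abs(spec$speeds))
  }
}

#' The standard murine compensatory eye-movement stimulus battery
#'
#' Convenience constructor for the session battery: resting position in the
#' light, 0.8 Hz +/-4.8 deg rotation in light (vision-enhanced) and darkness,
#' 0.4 Hz +/-4 deg sinusoidal optokinetic stimulation, and constant-velocity
#' optokinetic steps over +/-2.5-40 deg/s, about the yaw and roll axes.
#'
#' @return named list of `stimulus_spec` objects (plus a `resting_duration`
#'   element for the stationary determination).
#' @export
standard_battery <- function() {
  list(
    vvor = stimulus_spec("yaw", "sinusoid", "table",
                         frequency = 0.8, amplitude = 4.8, lighting = "light"),
    vor = stimulus_spec("yaw", "sinusoid", "table",
                        frequency = 0.8, amplitude = 4.8, lighting = "dark"),
    okr_yaw = stimulus_spec("yaw", "sinusoid", "planetarium",
                            frequency = 0.4, amplitude = 4, lighting = "light"),
    okr_roll = stimulus_spec("roll", "sinusoid", "planetarium",
                             frequency = 0.4, amplitude = 4, lighting = "light"),
    okr_steps_yaw = stimulus_spec("yaw", "velocity_steps", "planetarium"),
    okr_steps_roll = stimulus_spec("roll", "velocity_steps", "planetarium"),
    resting_duration = 20
  )
}
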