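#' Ground-truth parameters for a simulated oculography record
#'
#' Collects every quantity the synthetic-session generator needs and embeds
#' it in the record it produces, so analysis output can be checked against
#' known truth. Gains are dimensionless slow-phase response gains; an
#' asymmetric response is expressed through `gain_up`/`gain_down` (selected
#' by the sign of the stimulus velocity, positive = upward/positive
#' direction with respect to the recorded eye).
#'
#' @param gain slow-phase gain (used for both directions unless
#'   `gain_up`/`gain_down` are given). May also be a `data.frame(speed, gain)`
#'   lookup or a function of signed speed for step records.
#' @param gain_up,gain_down directional gains for asymmetric responses.
#' @param phase response phase in degrees; positive means the eye leads the
#'   stimulus.
#' @param drift_bias constant slow-phase drift superimposed on the response
#'   channel, deg/s (a vertical drift for roll-axis stimuli).
#' @param resting_h,resting_v resting eye position, degrees (horizontal re:
#'   session mean; vertical elevation re: earth-horizontal).
#' @param habituation total gain change accruing linearly over a session,
#'   post minus pre (negative = response decline). Applied by
#'   [simulate_session()]; a single record is generated at its session-time
#'   gain.
#' @param fast_phase_rate mean rate (per second) of scheduled resetting fast
#'   phases, in addition to eccentricity-triggered resets. Set 0 to disable.
#' @param fast_phase_times explicit fast-phase onset times (s); overrides
#'   `fast_phase_rate`.
#' @param arrest_intervals `data.frame(start, end)` of behavioral arrests
#'   (s), during which slow-phase drive decays and fast phases cease.
#' @param glissade_tau post-saccadic glissade time constant (s).
#' @param dropout_intervals `data.frame(start, end)` of pupil-tracking
#'   dropouts (s); `dropout_rate` (per second) draws them at random with mean
#'   duration `dropout_duration`.
#' @param dropout_rate,dropout_duration random dropout process parameters.
#' @param noise_sd additive Gaussian position noise, degrees.
#' @param seed integer seed; identical (spec, truth) pairs give bit-identical
#'   records.
#' @return an object of class `sim_truth`.
#' @export
sim_truth <- function(gain = 0.8, gain_up = NULL, gain_down = NULL,
                      phase = 0, drift_bias = 0,
                      resting_h = 0, resting_v = 15,
                      habituation = 0,
                      fast_phase_rate = 0.4, fast_phase_times = NULL,
                      arrest_intervals = NULL,
                      glissade_tau = 0.05,
                      dropout_intervals = NULL,
                      dropout_rate = 0, dropout_duration = 0.3,
                      noise_sd = 0.1, seed = 1L) {
  num_gain <- function(g, nm) {
    if (is.numeric(g) && (any(g < 0) || any(!is.finite(g)))) {
      stop(nm, " must be finite and >= 0")
    }
  }
  num_gain(gain, "gain")
  if (!is.null(gain_up)) num_gain(gain_up, "gain_up")
  if (!is.null(gain_down)) num_gain(gain_down, "gain_down")
  if (glissade_tau <= 0) stop("glissade_tau must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (fast_phase_rate < 0) stop("fast_phase_rate must be >= 0")
  structure(list(gain = gain, gain_up = gain_up, gain_down = gain_down,
                 phase = phase, drift_bias = drift_bias,
                 resting_h = resting_h, resting_v = resting_v,
                 habituation = habituation,
                 fast_phase_rate = fast_phase_rate,
                 fast_phase_times = fast_phase_times,
                 arrest_intervals = arrest_intervals,
                 glissade_tau = glissade_tau,
                 dropout_intervals = dropout_intervals,
                 dropout_rate = dropout_rate,
                 dropout_duration = dropout_duration,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  g <- if (!is.null(x$gain_up)) {
    sprintf("gain up %.3g / down %.3g", x$gain_up, x$gain_down)
  } else if (is.numeric(x$gain) && length(x$gain) == 1) {
    sprintf("gain %.3g", x$gain)
  } else "speed-dependent gain"
  cat(sprintf("<sim_truth> %s, phase %.3g deg, drift %.3g deg/s, seed %d\n",
              g, x$phase, x$drift_bias, x$seed))
  invisible(x)
}

## Signed slow-phase gain at a given stimulus velocity (deg/s). Handles
## scalar, directional, lookup-table and functional gain specifications.
truth_gain_at <- function(truth, stim_velocity, speed = NULL) {
  if (is.function(truth$gain)) {
    return(truth$gain(if (is.null(speed)) stim_velocity else speed))
  }
  if (is.data.frame(truth$gain)) {
    sp <- if (is.null(speed)) stim_velocity else speed
    idx <- match(sp, truth$gain$speed)
    if (any(is.na(idx))) stop("gain lookup table lacks speed ", sp[is.na(idx)][1])
    return(truth$gain$gain[idx])
  }
  if (!is.null(truth$gain_up)) {
    return(ifelse(stim_velocity >= 0, truth$gain_up, truth$gain_down))
  }
  rep(truth$gain, length(stim_velocity))
}
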