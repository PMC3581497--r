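# Shared stimulus fixtures for the suite. Records are always generated in
# code at test time; nothing is read from disk.

spec_vvor <- function(duration = 40) {
  stimulus_spec("yaw", "sinusoid", "table", frequency = 0.8, amplitude = 4.8,
                record_duration = duration)
}

spec_okr_roll <- function(duration = 40) {
  stimulus_spec("roll", "sinusoid", "planetarium", frequency = 0.4,
                amplitude = 4, record_duration = duration)
}

spec_steps <- function(speeds = NULL) {
  if (is.null(speeds)) {
    stimulus_spec("roll", "velocity_steps", "planetarium")
  } else {
    stimulus_spec("roll", "velocity_steps", "planetarium", speeds = speeds)
  }
}

# a clean record: no noise, no fast phases, no dropouts
quiet_truth <- function(gain = 0.5, drift_bias = 0, ...) {
  sim_truth(gain = gain, noise_sd = 0, fast_phase_rate = 0,
            drift_bias = drift_bias, ...)
}

# the declining speed-tuning gain table used for step-recovery checks
tuning_truth_table <- function() {
  mags <- c(2.5, 5, 10, 20, 40)
  data.frame(speed = as.vector(rbind(mags, -mags)),
             gain = rep(c(0.6, 0.5, 0.4, 0.25, 0.12), each = 2))
}
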