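# oculogain

Quantification of compensatory eye movements from murine video-oculography:
vestibulo-ocular reflex (VOR), vision-enhanced VOR (VVOR) and optokinetic
reflex (OKR) gains, for studies that ask whether an intervention (e.g. a
potassium-channel antagonist in an ataxic *Cacna1a* mutant) restores
depressed reflex amplitudes.

The package implements the complete measurement chain:

* **Calibration** — camera-yaw estimation of the pupil-to-rotation-center
  distance `Rp` and trigonometric conversion of pupil/corneal-reflection
  positions to angular eye position, including the cos(vertical) correction
  of the horizontal angle and the 20° nose-down mounting offset.
* **Desaccading** — detection of resetting fast phases on a short-window
  differentiator, patching by linear interpolation of the slow-phase
  velocity, exclusion of post-saccadic glissades, behavioral arrests and
  tracking dropouts.
* **Response metrics** — cycle-averaged Fourier gain and phase at the
  stimulus frequency; directional hemicycle gains from the regression
  `Y(t) = A sin 2πft + B cos 2πft + C` with amplitude `|Y| = √(A²+B²)`;
  constant-velocity step gains and speed-tuning curves; resting eye
  position; mean slow-phase velocity bias.
* **Session pipeline** — post-minus-pre deltas per measure, two-tailed
  pooled-variance t-tests between treatment arms (recomputed from the
  textbook summary-statistic formula), and dose–response regression of
  delta on injection volume with a control mean ± 2 SD reference band.
* **Dosimetry** — ejectate sphere volumetry (π d³/6), intrafloccular
  interstitial dilution, and volume-of-distribution serum/CSF estimates.
* **A synthetic session generator** producing ground-truth-annotated
  records — sinusoidal and constant-velocity batteries with configurable
  gain, phase, drift, fast phases, glissades, arrests, dropouts, noise and
  session habituation — so the whole pipeline is validated against known
  truth without animal recordings.

## Worked example

Simulate a 0.4 Hz ±4° sinusoidal roll-axis optokinetic record with gain
0.45, an upward drift of 0.29 °/s, and the default nystagmus model, then
run the full analysis:

```r
library(oculogain)

spec  <- stimulus_spec("roll", "sinusoid", "planetarium",
                       frequency = 0.4, amplitude = 4)
truth <- sim_truth(gain = 0.45, drift_bias = 0.29, seed = 11)
rec   <- simulate_sinusoidal_record(spec, truth)
rec
#> <oculo_record> roll planetarium sinusoid 0.4 Hz +/-4 deg; 40s at 500 samples/s (20000 samples); ground truth embedded

trace <- segment_record(rec)        # calibrate, label, patch
trace$labels
#> <segment_labels> 20000 samples: slow 95.4%, fast_phase 3.3%, glissade_excluded 1.3%, arrest 0.0%, dropout 0.0%, deleted_artifact 0.0%

fourier_gain_phase(average_cycles(trace))
#> <gain_phase> gain 0.454, phase -1.23 deg at 0.4 Hz (16 cycles; positive phase = eye leads stimulus)

hemicycle_gains(trace)
#> <hemicycle_gains> up 0.480 / down 0.470 at 0.4 Hz

mean_velocity_bias(trace)$bias
#> [1] 0.2764265
```

The recovered gain (0.454), phase (−1.2°), symmetric hemicycle split and
drift (+0.28 °/s) match the embedded truth (0.45, 0°, symmetric,
+0.29 °/s) to within the pipeline's validated tolerances: the 3.3% of
samples occupied by resetting fast phases have been detected and patched
rather than allowed to bias the Fourier amplitude.

Dosimetry calculations are closed-form:

```r
ejection_volume(100)                         # 100 um sphere -> pL
#> [1] 523.5988
100 * dilution_fraction(20, 400, 0.21)       # % remaining in flocculus
#> [1] 19.23077
serum_peak(1.25, 1036)                       # ng/mL
#> [1] 1206.564
csf_molar(serum_peak(1.25, 1036))            # uM
#> [1] 2.692078
```

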