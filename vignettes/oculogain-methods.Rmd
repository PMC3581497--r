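---
title: "Quantifying compensatory eye movements: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compensatory eye movements: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculogain)
```

# The measurement problem

Afoveate mammals such as mice stabilize their gaze with two reflexes: the
vestibulo-ocular reflex (VOR), driven by head rotation, and the optokinetic
reflex (OKR), driven by motion of the visual surround. Both are quantified
by their **gain** — the amplitude of the eye's slow-phase response divided
by the amplitude of the stimulus — and, for sinusoidal stimuli, by the
**phase** of the response relative to the stimulus. In mutants with
vestibulocerebellar dysfunction (e.g. *Cacna1a* calcium-channel mutants
such as *tottering*) these gains are depressed, and pharmacological studies
ask whether a treatment restores them. The experimental readout is a
video-oculography record: pupil and corneal-reflection positions tracked by
an infrared camera while a servo turntable rotates the animal or a
planetarium projector rotates a star field around it.

`oculogain` implements the full chain from raw camera signals to
session-level statistics:

1. **calibration** — trigonometric conversion of pupil coordinates to
   angular eye position;
2. **segmentation** — removal of everything that is not slow phase:
   tracking dropouts, resetting fast phases (saccades), post-saccadic
   glissades, behavioral arrests;
3. **response metrics** — sinusoidal gain/phase by cycle averaging and
   Fourier analysis, directional hemicycle gains by sinusoidal regression,
   constant-velocity step gains and speed-tuning curves, resting eye
   position, mean-velocity bias;
4. **session pipeline** — pre/post deltas, cohort t-tests, dose–response
   regression;
5. **dosimetry** — micro-injection volumetry and systemic concentration
   estimates;
6. **a synthetic session generator** that produces ground-truth-annotated
   records with the statistical structure the analysis assumes, so every
   stage is testable without animal recordings.

# Calibration geometry

The camera can be yawed by a known angle $\theta$ about a vertical axis
through the recorded eye; the pupil image is then displaced by
$R_p \sin\theta$, where $R_p$ is the effective distance from the pupil to
the eye's rotation center in camera units. `estimate_rp()` fits this slope
by least squares (an intercept absorbs reference offsets) and refuses
negative slopes, which indicate a flipped displacement channel.

`to_angles()` inverts the spherical projection:

$$v_{\mathrm{head}} = \arcsin\!\frac{p_v - r_v}{R_p}, \qquad
  h = \arcsin\!\frac{p_h - r_h}{R_p \cos v_{\mathrm{head}}}$$

The $\cos v$ factor is the vertical-position correction of the horizontal
angle: an elevated or depressed eye forecloses part of the horizontal
projection, and ignoring the correction biases $|h|$ toward zero (a
regression test asserts exactly this bias when the correction is switched
off). The animal is mounted with the skull axis pitched 20° nose-down, so
the head-frame vertical angle is offset by `pitch_offset` (default 20°) to
express elevation relative to the earth-horizontal plane. When
corneal-reflection channels are present they are subtracted from the pupil
channels first, removing camera-translation artifacts; the subtraction can
be disabled (`use_cr = FALSE`). Samples whose $\arcsin$ argument reaches
magnitude 1 are flagged invalid, never clipped; if more than half the
record is invalid the calibration itself is rejected.

The horizontal reference is each animal's average resting position. It is
taken as the session mean by default; a first-record mean would differ only
through within-session drift, and the session mean is the more stable
estimate.

# Sign and phase conventions

* Positive roll-axis stimulus velocity is **upward with respect to the
  recorded eye**; positive vertical eye position is elevation above
  earth-horizontal.
* Gains are reported positive for compensatory responses. For table
  (vestibular) stimuli the drive the eye follows is the **negated** table
  velocity; for planetarium (optokinetic) stimuli the eye follows the
  surround directly. A perfectly compensatory response therefore has gain 1
  and phase 0 in both cases.
* Positive phase means the eye **leads** the stimulus. Phases are wrapped
  to (−180°, 180°].
* Treatment-related changes are **post-treatment minus pre-treatment**.

# Velocity estimation

All gains are computed on velocity. Two differentiators are used, both
Savitzky–Golay polynomial-window filters at the 500 samples/s acquisition
clock:

* a **62 ms window** (31 samples, cubic) for slow-phase velocity. The
  window is still two orders of magnitude shorter than the 1.25–2.5 s
  stimulus periods (fundamental attenuation below 10⁻³), while halving the
  velocity noise relative to shorter windows; differentiator noise is the
  dominant random error in gain recovery, so the longer window directly
  tightens the recovered-gain distribution.
* an **18 ms window** (9 samples) for fast-phase *detection* only. A long
  window smears a 20 ms saccade and can attenuate the filtered peak
  velocity of a small (1.5°) resetting fast phase below any safe
  threshold; the short window preserves it.

# Desaccading (segmentation)

Nystagmus interleaves the compensatory slow phases with resetting fast
phases. The analysis must remove the fast phases — leaving them in biases
sinusoidal gain grossly (the validation suite demonstrates a bias above 0.1
on a standard fixture, versus ~0.01 after desaccading).

**Detection.** A sample is saccadic when its short-window speed exceeds
`max(velocity_threshold, expected peak slow-phase speed + peak_margin)`
(defaults 40 and +25 deg/s; the expected peak is $A\omega$ for a sinusoid
and the largest step speed for step records). An additive margin is used
rather than a multiple of the peak: for the ±40 deg/s step battery a
multiplicative rule (e.g. 3×) would demand 120 deg/s, far above the
filtered peak velocity of small resetting saccades, which would then pass
undetected and contaminate low-speed step gains. Supra-threshold runs
shorter than `min_fast_duration` (12 ms) are discarded as noise. Each
accepted run is grown: leftward to the flanking velocity minimum, and
rightward along the smoothed (9-sample moving average) monotone decay of
the post-saccadic tail, capped at 200 ms — this tracks the glissade down
into the noise floor. A further `post_fast_exclusion` window (40 ms, "the
first few tens of milliseconds") is labeled `glissade_excluded` after each
fast phase.

**Patching.** Fast-phase and glissade samples are patched by linear
interpolation **on the velocity traces**, between anchor values averaged
over up to five flanking slow-phase samples. Interpolating the *position*
trace literally would retain the saccadic displacement as a large spurious
velocity inside the patch; interpolating velocity is the standard
desaccading construction and is exactly what "joining the surrounding
slow-phase data" means once the saccadic displacement is discounted.
Patching never alters a slow-labeled sample (asserted as an invariant).
Intervals touching a record edge, or with no slow neighbor, are excluded
(`deleted_artifact`) rather than extrapolated. Dropouts — invalid samples
plus a 10 ms guard margin — are excluded, never patched.

**Behavioral arrests.** During constant-velocity stimulation mice may stop
making resetting fast phases; the eye then decelerates into an eccentric
halt. Arrest spans are excluded from gain. A span qualifies when the 0.2 s
smoothed speed stays below `arrest_velocity_fraction` (0.2) of the step's
**expected slow-phase speed** for at least 300 ms. The expected speed is
estimated per step as the median smoothed speed of the step's eligible
samples (floored at 2 deg/s): the stimulus speed itself would overstate it
badly at high speeds, where optokinetic gain is small, and would flag
entire healthy steps as arrested. Detected spans are extended into the
deceleration and reacceleration flanks (up to 0.5 s each way, until the
speed returns to 80% of cruise). A step with fewer than 10% slow samples
is reported unusable rather than imputed. "Non-alertness" exclusions in
real data are operationally the same arrest-like spans; manual exclusion
lists are supported through the session manifest.

# Response measures

**Cycle average and Fourier gain/phase.** Complete stimulus cycles are
folded onto 100 phase bins; a cycle contributes to a bin only if every one
of its samples there is usable (patched samples count, dropouts do not),
and at least 3 clean cycles are required — fewer is an error, not a
warning. The fundamental amplitude and phase of the response and stimulus
velocity are extracted by weighted sinusoidal regression over the bins
(weights = per-bin cycle counts, robust to bins emptied by dropouts);
gain is the amplitude ratio and phase the difference.

**Hemicycle gains.** Directional (upward vs downward) gains for sinusoidal
roll OKR follow a five-step procedure: segment and patch; fit the stimulus
velocity with a sinusoid; split samples by the sign of the fitted stimulus
velocity; regress $Y(t) = A\sin 2\pi f t + B\cos 2\pi f t + C$ by ordinary
least squares separately per hemicycle for eye and stimulus, on per-sample
(not cycle-averaged) data; form amplitudes $|Y| = \sqrt{A^2+B^2}$ and take
the eye/stimulus ratio. A hemicycle with under 25% usable samples is
reported missing. On a symmetric noiseless record the hemicycle gains
equal the full-cycle Fourier gain to numerical tolerance (asserted).

**Step gains and speed tuning.** A step's gain is the mean slow-phase eye
velocity over its *slow-labeled* samples divided by the planetarium
velocity — patched saccade windows are excluded from the mean, since the
interpolated samples carry no independent information and only dilute the
estimate. Per-speed gains are averaged across repetitions into a
speed-tuning curve; `delta_curve()` aligns post and pre curves on their
shared speed set and subtracts.

**Additive-drift law.** A constant drift $v$ superimposed on the response
changes a step gain by exactly $v/s$ at speed $s$, and leaves full-cycle
sinusoidal gain essentially unchanged (< 0.005), because a DC term is
orthogonal to the fundamental. Both are verified against the closed form.
At $+2.5$ deg/s a 0.2 deg/s drift therefore shifts gain by exactly
$0.2/2.5 = 0.08$; the figure of "about 0.1" sometimes quoted for this
configuration is the rounded form of the same arithmetic, and the package
asserts the exact value.

**Resting position** averages eye position over stable spans (0.2 s
smoothed speed below 1.5 deg/s for at least 0.5 s). A transient eccentric
hold — a saccade away from the equilibrium region with equilibrium spans
both before and after — is excluded; if distinct stable levels remain with
no identifiable equilibrium, all stable spans are averaged; if no stable
span exists (pure drift), the whole-record mean is used.

**Mean-velocity bias** is the DC term of the patched slow-phase eye
velocity, identical by construction to the coefficient $C$ of the
sinusoidal regression over the full record. It is reported as actual eye
velocity (deg/s), not in the compensatory convention.

# The synthetic session generator

Because no public recordings exist for this preparation, validation rests
on a generator that emulates the stimulus battery and the disturbances the
analysis must survive. Its defaults are the study conditions, chosen once:

| Parameter | Default | Meaning |
|---|---|---|
| sample rate | 500 /s | acquisition clock |
| `video_rate` | off (optional 120 Hz) | camera sample-and-hold stage |
| rotation stimulus | 0.8 Hz ±4.8° | vestibular sinusoid (light or dark) |
| optokinetic sinusoid | 0.4 Hz ±4° | yaw or roll planetarium |
| step battery | ±{2.5, 5, 10, 20, 40} deg/s | 4 s steps, 3.5 s dark gaps |
| record length | 40 s (sinusoids) | complete cycles only are analyzed |
| position noise | 0.1° SD Gaussian | video tracking noise |
| fast-phase rate | 0.4 /s scheduled | plus resets at 8° eccentricity |
| fast-phase shape | 20 ms, 20% overshoot, ≥1.5° | raised-cosine pulse |
| glissade | 15% of saccade, τ = 50 ms | pulse-step mismatch |
| resting vertical | 15° | elevated, mutant-like |
| session gain SD | 0.05 | between-session baseline spread |
| habituation SD | 0.05 | between-session spread of the pre→post change |
| injection volumes | lognormal, median ≈ 300 pL, clipped 0.4–1100 pL | intrafloccular series |

Slow-phase velocity is constructed analytically (gain × phase-shifted
stimulus velocity + drift), integrated to position, and fast phases are
inserted as displacement waveforms: a raised-cosine pulse that carries the
eye past center by the overshoot fraction, followed by an exponential
glissade returning the overshoot. Resets trigger at the eccentricity
threshold (suppressed during arrests, disabled entirely with
`reset_threshold = Inf` for closed-form tests) and at scheduled Poisson
times. Arrests decay the slow velocity exponentially (τ = 150 ms) to a
held eccentric position. Dropouts blank the pupil channels. The realized
event intervals, the true slow-phase velocity, and every parameter are
embedded in the record, so recovery tests compare against exact truth.
Identical (stimulus, truth, seed) triples give bit-identical records.

Habituation — the decline of gain over a recording session — is applied as
a linear ramp summarized by its pre→post difference, since only pre/post
contrasts are analyzed. In `simulate_session()` the pre-phase gain is the
cohort baseline plus a session offset (SD 0.05), and the post-phase gain
adds the habituation (itself varying between sessions, SD 0.05 — the
dominant source of delta spread, consistent with reported saline-arm SDs
of roughly 0.04–0.09) plus any treatment effect.

**What the generator does not emulate:** ocular plant dynamics (the slow
phase is kinematically prescribed, not produced by a plant model), video
frame rendering and pupil-tracking failure modes beyond dropouts,
torsional eye position, drug pharmacodynamics, and any dependence of
fast-phase statistics on stimulus or state beyond the reset threshold.
Passing the validation suite therefore shows that the analysis recovers
known parameters under realistic noise, nystagmus, arrests and dropouts —
it does not certify performance on artifacts the generator does not
produce (e.g. slow tracking-loss drifts or chewing transients that mimic
slow phases).

# Dosimetry

Four closed-form calculations support injection experiments:

* `ejection_volume(d)` = $\pi d^3/6$, the paraffin-oil sphere volumetry of
  the pressure-injection ejectate (µm → pL).
* `dilution_fraction(v, V, f)` = $v/(v + fV)$: the residual concentration
  fraction when a bolus $v$ expands into the accessible interstitial
  fraction $f$ of a structure of volume $V$. The default denominator
  includes the bolus (mass conservation). The variant excluding it is
  available (`include_injectate = FALSE`) because the arithmetic behind a
  rounded "about 20%" for 20 nL into 21% of 400 nL is ambiguous between
  19.2% and 23.8%; both conventions are provided and the inclusive one is
  the default.
* `serum_peak(dose, Vd)` = dose/Vd (mg/kg over mL/kg → ng/mL), the peak
  serum level of a fully absorbed, fully equilibrated bolus; default Vd
  1036 mL/kg for 4-aminopyridine.
* `csf_molar(serum, ratio, M)` = serum × ratio / M (→ µM), with the
  CSF:serum ratio 0.21 and M = 94.12 g/mol for 4-aminopyridine.

# Session statistics

Deltas are post − pre per session and measure. `compare_groups()` computes
the textbook pooled-variance two-tailed t statistic from the group
summaries itself (`t_from_summary()` is exported; `stats::t.test` serves
as an independent cross-check in the test suite), plus paired tests of
post vs pre. Degenerate variance is reported, not fatal: identical groups
give t = 0, p = 1. Each session is one observation by default, matching
reported per-arm n's even though each animal typically contributes two
sessions per arm; `by_animal = TRUE` averages within animal first. No
multiple-comparison correction is applied by default, matching common
practice in this literature; `stats::p.adjust(..., "holm")` can be applied
to the returned p-values by the user. Outlier sessions are never dropped
automatically — the session manifest supports an explicit exclusion list
with reasons. `dose_response()` regresses delta on injection volume by
ordinary least squares and computes the control reference band
(mean ± 2 SD of designated control sessions, poolable across dosage
series).

# Validation problem sizes and tolerances

The acceptance suite (and `scripts/acceptance.R`) uses: 100 seeded
sinusoidal records with gains in [0.1, 1] (median |gain error| < 0.01, max
< 0.03, mean |phase error| < 2°); 50 asymmetric + 25 symmetric hemicycle
records (means within ±0.03; mean up/down split < 0.02); the ±2.5–40 deg/s
step battery in a paired drift design (deviation from drift/speed
< 0.005); a desaccading fixture (0.4 Hz ±4° roll OKR, gain 0.5, 0.5 deg/s
drift, 4° reset threshold) on which the unpatched gain bias exceeds 0.1
while the full pipeline stays within 0.02; 15–20 replicate experiments of
12 + 12 sessions for the habituation (−0.06) / treatment (+0.08)
decomposition, detected at p < 0.05 in at least 80% of replicates; and
40-session injection series for the null-calibration and slope recovery of
the dose–response regression. Step-gain recoveries average four
repetitions per speed, the usual repetition count for constant-velocity
batteries. These sizes keep the full suite within a few minutes on one
core while leaving the statistical margins comfortable.

Known numerical edge cases: records shorter than 3 stimulus cycles are
rejected; a stimulus with ~zero fundamental amplitude yields an undefined
gain (error); all-equal injection volumes make the dose–response
regression degenerate (error); a fully arrested step is a missing value
with a reason, not a zero.

# Limitations

The package quantifies horizontal/vertical eye position only — no torsion,
no 3-D kinematics. Fast-phase detection assumes saccadic peak velocities
well above the slow-phase ceiling; stimuli whose slow phases approach
saccadic speeds would need a different detector. The arrest classifier's
expected-speed estimate assumes less than about half of a step is
arrested; steps arrested from onset are flagged unusable rather than
salvaged. The t-tests treat sessions as independent unless
`by_animal = TRUE`; neither option is a substitute for a mixed-effects
model when animals contribute many sessions.
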