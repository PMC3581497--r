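Package: oculogain
Title: Quantification of Compensatory Eye Movements from Video-Oculography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for murine video-oculography: trigonometric
    calibration of pupil/corneal-reflection signals to angular eye position,
    desaccading of nystagmus (fast-phase detection, linear-interpolation
    patching, behavioral-arrest and post-saccadic-glissade exclusion),
    Fourier gain and phase of sinusoidal vestibulo-ocular and optokinetic
    responses, hemicycle sinusoidal-regression gains, constant-velocity
    speed-tuning curves, resting eye position, and mean-velocity bias.
    Includes a ground-truth-annotated synthetic oculography session
    generator for validation, micro-injection dosimetry calculations
    (ejectate sphere volumetry, intrafloccular dilution, systemic
    serum/CSF concentration estimates), and session-level orchestration
    with pre/post deltas, cohort t-tests and dose-response regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
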