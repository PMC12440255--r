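Package: nidot
Title: Infant HD-DOT Prediction-Error Analysis with Gaze-Modulated GLMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for infant functional
    near-infrared / high-density diffuse optical tomography (HD-DOT)
    experiments on prediction error. Generates synthetic cohorts with the
    paradigm's timing, gaze, optical and anxiety-coupling structure;
    computes per-trial dwell-time ratios from eye-tracking; cleans
    two-wavelength optical-density channel data (motion detection, spline,
    wavelet and temporal-derivative-distribution-repair correction,
    band-pass filtering, modified Beer-Lambert conversion, epoching);
    performs analytic semi-infinite forward modelling, zeroth-order
    Tikhonov image reconstruction and sensitivity-weighted region-of-
    interest aggregation; fits FIR and canonical-HRF GLMs with a
    gaze-engagement parametric modulator by AR-prewhitened robust
    regression; and runs random-intercept mixed models, trait-anxiety
    interaction models and logistic prediction of clinical anxiety at the
    group level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
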