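---
title: "Models and methods behind nidot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nidot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nidot)
```

nidot implements the full analysis chain for an event-related infant
HD-DOT prediction-error experiment with concurrent eye-tracking: synthetic
cohort generation, dwell-time-ratio (DTR) engagement measurement,
channel-space optical preprocessing, forward modelling and Tikhonov image
reconstruction, gaze-modulated GLMs, and group-level mixed-model inference.
This vignette documents the models, the parameter defaults and their units,
the numerical choices, and the places where the design was genuinely open.

## The paradigm and the synthetic cohort

A session is a sequence of trials: a 750-ms auditory cue, then a 1800-ms
stimulus window in which the cued cartoon appears with probability 0.8
("expected") or is omitted ("unexpected"), separated by uniformly jittered
3-5-s baselines. `generate_trial_schedule()` reproduces exactly this
timing; a 27-trial default session gives roughly 22 expected and 5
unexpected trials, and subjects with fewer than 3 usable trials of either
type are excluded (`subject_inclusion()`).

The generator's defaults *are* the study conditions, chosen once:

* **Engagement.** Per-trial true DTR follows
  `dtr = intercept + (-0.10) * unexpected + (-0.014) * (trial - 1) + eps`,
  clamped to [0, 1], with trial noise SD 0.18 and subject intercepts drawn
  from N(0.68, 0.22) clamped to [0.05, 0.98]. The -0.10 condition effect
  and the -0.014/trial habituation slope are the planted analogues of the
  trial-level engagement effects the analysis is meant to recover. The
  between/within variance split was calibrated once so that the
  condition-only random-intercept model on generated cohorts yields a
  conditional R-squared near 0.48 with a small marginal R-squared — the
  regime in which subject-level variability dominates and a parametric
  engagement modulator is genuinely needed.
* **Responses.** Subject amplitudes are in uM HbO: expected ~ N(0.4, 0.08),
  unexpected `b0 + b1 * trait + u + eps` with `b0 = 0.3`, trait-anxiety
  slope `b1 = 0.01` uM per STAI point, a shared per-subject responsiveness
  component `u ~ N(0, 0.1)` (responses correlate across conditions within
  an infant, which is what the group-stage random intercept absorbs), and
  `eps ~ N(0, 0.12)`. HbR is planted at -1/3 of HbO, the canonical
  oxy/deoxy ratio. STAI scores are truncated-normal N(36, 9) on [20, 80];
  trait > 40 flags clinically elevated anxiety. 25 of 31 subjects carry
  maternal scores, mirroring the respondent rule of the anxiety analyses.
* **Attention coupling.** Trial amplitude is
  `beta_condition * (a + (1 - a) * dtr_true)` with `a = 0.5` by default:
  at `a = 1` the response is engagement-independent, at `a = 0` it is fully
  gated by looking time. The form is a package invention (no published
  coupling law exists); `a` is a configuration parameter.
* **Optical noise.** Channel OD traces carry white noise (SD 0.01 OD),
  AR(1) noise (phi 0.4, SD 0.01), sinusoidal drift (0.02 OD at 0.002 Hz),
  a cardiac line at 2.0 Hz (below the 2.3-Hz Nyquist frequency of the
  4.6-Hz acquisition; infant heart-rate realism is secondary to exercising
  the filters), exponentially decaying spikes (0.5/min, ~0.25 OD) and
  persistent baseline shifts (0.2/min, ~0.15 OD), all echoed into the
  ground-truth record. Spike amplitudes are an order of magnitude above
  the noise floor, as real motion transients are.

What the generator does *not* emulate: spatially structured physiology
(systemic superficial signals, respiration), distance-dependent channel
noise, head-size variation, or optode-coupling drift. Tests passing on
synthetic cohorts therefore validate the algorithmic chain and its
statistical calibration, not robustness to every physiological confound of
real infant recordings.

## Gaze and the DTR

`compute_dtr()` attributes samples to the window [cue onset, cue onset +
2.55 s) by timestamp (half-open), excludes invalid samples from numerator
and denominator, and marks trials with zero valid time as missing rather
than zero. No interpolation is performed across dropout gaps — the
valid-time denominator is the recommended treatment for infant signal
loss. `scale_dtr()` applies the fixed affine map from the theoretical
[0, 1] domain to [0.1, 1]; a fixed map (rather than per-subject min-max)
keeps the modulator comparable across subjects and is well-defined for
constant series. Trials with missing DTR are dropped from all event
regressors rather than imputed.

## Channel-space preprocessing

Two presets encode the two processing orders:
image branch `detect -> spline -> wavelet -> band-pass -> prune -> MBLL ->
epoch`, and ROI/GLM branch `trim/resample -> TDDR -> MBLL -> ROI -> GLM`.

* **Motion detection** flags any 1-s window whose peak-to-peak OD change
  exceeds 0.4 OD or 15 times the channel's SD of successive differences,
  dilated by 1 s. The detection contract (thresholds plus dilation) is
  specified and validated against planted artifacts rather than
  reproducing any particular toolbox's windowing internals.
* **Spline correction** fits a smoothing spline inside each masked
  segment, subtracts it, and re-levels segments sequentially so persistent
  baseline steps inside a mask are repaired; later clean data are
  level-aligned (a constant shift), which is the price of repairing
  steps. The parameter p = 0.99 is stated in the MATLAB `csaps`
  convention; `smooth.spline` rescales x to [0, 1], so the penalty is
  mapped as `lambda = ((1 - p)/p) / (n - 1)^3` on unit-spaced samples.
* **Wavelet correction** runs a periodized db2 discrete wavelet transform
  (written in-package) to depth `floor(log2(N)) - 1` after reflection
  padding to a power of two, zeroes detail coefficients outside the
  quartile fences `Q1/Q3 -/+ 0.8 IQR`, and reconstructs. Levels with fewer
  than 16 coefficients are left untouched — quartile fences are
  meaningless on a handful of samples, and this preserves exact
  reconstruction of benign data.
* **TDDR** splits each channel at 0.5 Hz (the split frequency of the
  method's original description), iterates Tukey bisquare weights
  (c = 4.685, MAD scale, weighted-mean centering) on the slow component's
  first differences to convergence (max weight change < 1e-6 or 50
  iterations), multiplies the differences by the final weights,
  re-integrates and adds the fast component back. Constant and linear
  channels are untouched by construction. Sub-second transients partly
  live above the 0.5-Hz split and are only attenuated — that is inherent
  to the method and is why the spline/wavelet steps precede band-passing
  in the image branch.
* **Band-pass** is a Hamming-window linear-phase FIR applied
  forward-backward (zero phase, so bin-indexed FIR averages downstream are
  not latency-shifted). Meeting 20 dB stopband attenuation at half the
  0.01-Hz low edge requires roughly 3000 taps at 4.6 Hz, i.e. recordings
  of 16+ minutes; shorter recordings either error with the minimum length
  (default) or, with `strict = FALSE` (the pipeline preset), use the
  longest realizable order with a warning. Filter-response tests evaluate
  the designed filter's transfer function directly.
* **MBLL** inverts `dOD(lambda) = [eps_HbO dHbO + eps_HbR dHbR] * d * DPF`
  per source-detector pair with DPF = 5.1 at both wavelengths (a single
  infant-appropriate value) and extinction coefficients from the
  Gratzer/Prahl compilation at the default 735/850 nm (natural-log
  convention, mm^-1 uM^-1). Pairs missing a wavelength are dropped and
  recorded. OD is natural-log throughout.
* **Epoching** cuts 9-s windows from 2 s before stimulus onset and
  subtracts the 2-s pre-onset baseline mean per epoch and channel. With
  3-5-s baselines, neighbouring responses overlap the baseline window, so
  block averages are attenuated estimates — one reason the FIR GLM, which
  models overlap by superposition, is the primary analysis.

## Forward model, reconstruction and ROIs

Fluence modelling uses the analytic CW diffusion Green's function for a
homogeneous semi-infinite medium with an extrapolated boundary (default
mua = 0.017 mm^-1, musp' = 0.74 mm^-1, n = 1.4; sources buried at one
transport mean free path). The Rytov/adjoint sensitivity is
`J[c, n] = G(s, n) G(n, d) / G(s, d) * V`. This stands in for segmented
finite-element fluence modelling of an infant head; the algebraic
interfaces (Jacobian in, images out) are identical, but absolute ROI
placement on a real cortex is out of scope, so the six regions — left and
right mPFC, medial SFG and middle PFC — are disks on the toy cortex at
fixed coordinates.

Zeroth-order Tikhonov reconstruction solves
`x = J' (J J' + lambda * max(diag(J J')) I)^-1 y` with lambda = 0.01; the
scaling by the largest diagonal entry of `J J'` makes the dimensionless
hyperparameter transferable across probes and is recorded in the result.
Two-wavelength absorption images are unmixed per node through the same
extinction matrix the MBLL uses. ROI channel weights are proportional to
the summed absolute sensitivity over the region's nodes, normalized over
channels admitted by the 12-45-mm separation window.

## The GLM stage

`build_design()` produces, per condition, either 28 FIR bin regressors
(unit impulses at post-onset lags 0..27 samples) or a canonical regressor
(onset impulses convolved with the canonical HRF
`h(t) = (t/4)^6 exp(6 (1 - t/4))`, peak 1 at 4 s), plus one engagement
modulator (onset impulses with scaled-DTR heights convolved with the
canonical HRF, applied across all trials irrespective of condition, not
orthogonalized), an intercept and a linear drift. Near-collinearity
(condition number > 1e6, e.g. a constant DTR series) and FIR spans
exceeding the inter-trial spacing raise warnings; overlap is handled by
linear superposition.

**Bin-to-time convention.** Bin b covers `[(b - 1)/rate, b/rate)` seconds
post-onset, so a literal reading of "bins 12-24" at 4 Hz is 2.75-6.00 s.
The peak-window label "3 to 6 s" is honored by the default `"onset-label"`
convention, which maps the 12-24 label to internal bins 13-24, a window of
exactly [3.00, 6.00) s; the literal convention remains available and the
mapping is part of the fit output.

**AR(P)IRLS.** Fitting iterates: Tukey bisquare IRLS (c = 4.685, 95%
Gaussian efficiency) on the whitened model; AR order selection by BIC over
orders 0..ceiling(4 * rate) via Levinson-Durbin on outlier-robust
autocovariances; whitening of data and design with the selected filter.
The autocovariances exclude sample pairs involving amplitude outliers, and
spikes are re-detected in the innovation (whitened) domain, where they
stand out against the compressed noise, before a final re-estimate — plain
moment or robust-regression AR estimators are measurably attenuated by
additive spikes (an errors-in-variables effect), which under-whitens and
mis-calibrates the standard errors. The AR structure is frozen after three
outer iterations, and the loop stops when the coefficient vector changes
by less than 1e-4 (relative) or after 20 iterations, with a warning on
non-convergence. Standard errors come from the whitened weighted normal
equations with the Huber mean-psi-derivative correction; with
`tukey_c = Inf` and `max_ar_order = 0` the fit reduces exactly to ordinary
least squares. Calibration was verified by simulation: 95% CI coverage of
a planted amplitude is 0.94 (300 replicates) under AR(1) noise (phi 0.6)
with 5% spike contamination at the generator's spike scale.

**Truncation.** A 28-bin FIR at 4 Hz spans 7 s while the canonical kernel
has support near 24 s; the unmodelled tail attenuates bin-average
estimates by roughly 15% under the default schedule. Exactness tests
therefore use an FIR spanning the kernel support (96 bins), where the
noiseless recovery is exact to machine precision; the 28-bin default
matches the field's practice and its estimates are interpreted as
windowed, not absolute, response amplitudes.

**What the engagement-adjusted contrast estimates.** Under the coupling
`amplitude = beta_c (a + (1 - a) dtr)`, a model with one shared modulator
cannot return the raw planted difference `d = beta_U - beta_E`: collapsing
the GLM to its per-trial amplitude projection shows the fitted U - E
contrast converges (and in the no-noise collapsed problem, is exactly
equal) to the *attention-referenced* contrast
`d * (a + (1 - a) * d_tilde)`, where `d_tilde` is the cross-condition
engagement reference `w * mean(dtr_U) + (1 - w) * mean(dtr_E)` with
`w = n_E S2_E / (n_E S2_E + n_U S2_U)` — the contrast evaluated at a
common engagement level. The mechanism tests compare both model variants
against this quantity: with the modulator the estimate is unbiased (within
Monte-Carlo error over 500 replicates), and without it the estimate
carries the engagement-confound bias (about -0.028 uM here, more than 5
Monte-Carlo standard errors), reproducing the qualitative finding that
condition effects emerge only when engagement is modelled.

Group contrasts (unexpected vs baseline and unexpected minus expected, per
ROI and chromophore) are one-sample t-tests over subjects of the
bin-averaged betas, pooled into the Benjamini-Hochberg step-up correction
with m = 12 (6 ROIs x 2 contrasts) at FDR 0.05; `fdr_bh()` is a direct
implementation of the step-up rule, cross-checked against `p.adjust`.

## Group models

`fit_random_intercept()` wraps REML estimation with Satterthwaite
fixed-effect tests (the fractional degrees of freedom convention); ML is
switchable, and the log-likelihood was verified against a brute-force
numerically integrated likelihood on small cohorts. Variance-partition
R-squared uses `var_fixed / (var_fixed + var_subject + var_resid)`
(marginal) and `(var_fixed + var_subject) / (...)` (conditional), with
`var_fixed` the variance of the fixed-effect predictions. The anxiety
model `beta ~ -1 + condition + condition:trait_anxiety + (1 | subject)`
reports per-condition intercepts and trait slopes; the slope on the
unexpected condition is the quantity of interest, and the state-anxiety
control model has the same structure. Logistic prediction of the clinical
flag (trait > 40) from the unexpected-event response reports Wald
statistics and flags (quasi-)separation instead of claiming finite
estimates. Degrees of freedom are reported per fitted model; pooled-df
conventions from channel-level fits are not reverse-engineered.

Simulation calibration at the study's n = 25: the planted 0.01 uM/point
trait slope is recovered with 98% sign-consistency, and null cohorts
reject at 5-7% at alpha = 0.05 (500 replicates each). Single cohorts at
n = 25 are underpowered for significance of this effect size — the
analysis scripts therefore report replication summaries alongside the
single-cohort fits.

## Problem sizes and reproducibility

The test suite and analysis scripts run at desk scale by choice: 27-trial
sessions, 31-subject cohorts for gaze analyses (200 subjects for the
recovery study), 25-subject anxiety cohorts, 2-4-tile probes for
channel-level integration tests (the full 12-tile, 1728-channels-per-
wavelength layout is exercised where only geometry matters), 300-500
replicates for the calibration studies. Every generator takes an explicit
seed, restores the caller's RNG stream, and the pipeline derives all
per-subject seeds from a single master seed, so runs are bit-reproducible;
results carry a configuration hash.

## Known limitations

The analytic forward model ignores layered optics and curvature, so image
amplitudes are not quantitatively calibrated (the image branch is treated
as visualization, as is conventional). The wavelet and spline corrections
follow published parameterizations but not any toolbox's exact code path.
The engagement coupling law is an assumption; real attention effects on
hemodynamics need not be linear in DTR. SNIRF/HDF5 containers are not
read or written — channel data travel as CSV matrix + channel table +
JSON sidecar.
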