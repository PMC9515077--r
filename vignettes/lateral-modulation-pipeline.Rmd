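---
title: "Modeling lateral modulation and perceptual filling-in: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling lateral modulation and perceptual filling-in: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scotomafmri)
```

## The scientific problem

When a peripheral pattern surrounds a central patch, the neural response to
the patch changes — usually it is suppressed. A striking perceptual
consequence is filling-in of an *artificial scotoma*: after steady
fixation, a blank region embedded in a surrounding texture fades and the
surround pattern appears to spread into it. `scotomafmri` implements a
complete, reproducible analysis pipeline for an event-related fMRI
paradigm that probes both phenomena with center-surround radial sinusoidal
gratings:

* a **full-field** radial grating,
* a **center** grating confined to two crescent patches at 8°
  eccentricity (one per hemifield), and
* a **scotoma** grating — the pixelwise complement of the center grating —
  whose blank crescents can perceptually fill in (observers report fill /
  no-fill on every scotoma trial).

The two scientific contrasts are (1) Full-Field − Center in the cortical
projection zones of the crescents, where surround suppression predicts a
*negative* difference, and (2) Fill − No-Fill among scotoma trials, where
the interesting outcome is a *dissociation*: no difference in mean BOLD
amplitude, but a decodable difference in the multivoxel pattern.

## Stimulus model

The full-field grating is `G = B + B·C·cos(2π·f·θ)` with `θ` the rotation
angle (polar angle) in degrees, so `f` is in cycles per degree of rotation
angle: `f = 0.1` gives 36 spokes around the display. The center grating
multiplies the modulation by an annular window

`W = exp(−(((r − r_E)² / (2σ_r²))^P))`

(`r_E = 8°`, `σ_r = 1°`, `P = 3` for the soft-edged main stimuli, `P = 1000`
for the sharp-edged localizer) and by a mask that zeroes ±30° of rotation
angle around both vertical meridians, leaving two 120° crescents (arc
length `8° · 2π/3 ≈ 16.8°` of visual angle). The scotoma grating is the
complement: `(center − B) + (scotoma − B) = (full_field − B)` holds at
every pixel by construction, and the composition test asserts it exactly.

Design choices the display literature does not fix:

* **Rotation-angle origin.** 0° at the upper vertical meridian, increasing
  clockwise; configurable, and nothing downstream depends on it because
  the mask is symmetric about the vertical meridian.
* **Crescent width.** We define the printed 2.8° radial width as the width
  of the window at its `1/e` contour. At that contour the exponent is
  exactly 1 for *every* power `P`, giving `2·√2·σ_r ≈ 2.83°`; the
  half-maximum contour would instead give 2.66° and varies in
  interpretation, so the `1/e` definition is the one the package adopts
  (`crescent_geometry()`).
* **Counterphase flicker.** "5 Hz" is read as five full contrast-reversal
  cycles per second, i.e. a sign change every 6 frames at 60 Hz
  (`flicker_sequence()`).
* **Luminance.** Normalized [0, 1] units; display gamma is hardware
  calibration and out of scope.

## Experiment designs

`retinotopy_timing()` encodes the rotating-wedge / expanding-ring session:
a 22.5° wedge step per 3-s TR gives a 48-s rotation cycle; the ring
expanding 0.25°→10.6° in 0.86° steps gives 12 steps = 36 s. The step count
uses the *nearest* integer of range/step — the final step is truncated at
the edge of the mapped field — because the printed cycle lengths and the
6/8 cycles per 96-TR run are only mutually consistent under that
convention. `localizer_design()` is the 6-on/6-off × 6 block checkerboard
localizer (72 TRs). `main_experiment_sequence()` draws, per run, a seeded
permutation of 5 Center + 5 FullField + 10 Scotoma trials at a 24-s trial
period (10 s on, 14 s off; TR 2 s), so 8 runs give 40/40/80 trials.
`pretest_staircase()` encodes the contrast-titration rule (more than 6 of
10 fill reports → increase; fewer than 4 → decrease). The pre-test step
size is not specified by the protocol; the staircase here only reports the
direction.

## Synthetic data: what it emulates and what it does not

No public dataset accompanies this paradigm, so `simulate_bold()`
generates per-ROI voxel × TR series with exactly the structure the
analyses assume:

* signal = baseline + Σ condition amplitude × HRF-convolved unit-peak
  boxcar, on a percent-signal-change scale (baseline 100, amplitudes
  0.5–2);
* surround suppression as an amplitude decrement of FullField relative to
  Center (default 0.3% on 1.5%);
* the Fill/NoFill dissociation as two fixed, orthogonal, **zero-sum**
  voxel pattern vectors added to a shared scotoma amplitude — the ROI mean
  carries no report information while the pattern does;
* AR(1) Gaussian noise (marginal SD 1, lag-1 correlation 0.3) plus an
  optional linear drift (off by default);
* fill reports as Bernoulli(0.5) per scotoma trial, drawn once per
  participant and shared across that participant's ROIs.

The double-gamma HRF (`hrf_double_gamma()`) peaks at 5 s with a ~15-s
undershoot, normalized to unit peak. Because the generator and the GLM
share `build_design()`, the noiseless limit recovers the injected
amplitudes exactly — the package's strongest internal consistency check.

`pattern_strength` was calibrated once so that leave-one-run-out decoding
of the fill report lands in the 60–80% accuracy band (0.15% per-voxel
pattern SD at the default noise level); weaker values approach chance and
stronger ones saturate at 100%, neither of which exercises the inference
machinery realistically.

`simulate_gaze()` draws fixation positions whose stationary marginal is
exactly the requested bivariate normal, with three deliberate features:
slow AR(1) drift (per-sample coefficient 0.9) so that consecutive-sample
velocities stay in the physiological few-deg/s range; blink gaps flagged
invalid; and saccadic spikes of 1.5–4°. Spikes last a single sample
because the cleaning rule only velocity-tests intervals between
*consecutive surviving* samples (intervals spanning a removed gap are not
tested — otherwise gaps would fabricate giant velocities); a multi-sample
excursion would therefore partially survive cleaning. This is a known
limitation of velocity-threshold cleaning generally, not only of the
simulation. A consequence of the drift is that n gaze samples carry about
`n(1−φ)/(1+φ)` independent observations, so tight BCEA-recovery checks use
long records (10⁵ samples) rather than the nominal 10⁴.

What the generator does **not** emulate: retinotopic cortical geometry,
physiological noise regressors, attention fluctuations, partial or
time-varying filling-in, and any dependence of the report on the stimulus
itself. Passing tests therefore certify the *analysis machinery* —
estimator correctness, calibration of the statistical tests, recovery of
injected effects — not claims about real cortical data.

## GLM and group inference

`build_design()` makes one HRF-convolved boxcar regressor per condition
(Fill and NoFill modeled as separate regressors so their contrast is
estimable), each scaled to unit single-trial peak so coefficients are peak
percent signal change, plus an intercept. `fit_glm()` concatenates runs
with one intercept per run (absorbing between-run offsets) and fits
ordinary least squares per voxel — deliberately without prewhitening, as
"standard GLM" practice; the AR(1) noise in the generator is exactly the
perturbation this choice must be robust to, and the calibration tests
confirm the group-level error rates stay nominal. `contrast_t()` computes
`t = c'β / √(σ̂²·c'(X'X)⁻¹c)`; `normalize_beta()` divides condition
coefficients by the voxel's mean run intercept (the "baseline"), making
amplitudes dimensionless and scale-invariant. Group inference
(`group_test()`) is a one-sample t-test across participants on ROI-mean
contrast t values — one-tailed *less* for Full-Field − Center (the
suppression hypothesis), two-sided by default for Fill − NoFill since the
direction is not specified a priori — with Cohen's d = t/√n and
Bonferroni-corrected alphas (0.05/12 for the univariate family: 6 ROIs × 2
contrasts; 0.05/3 for MVPA).

## Time courses

`epoch_trials()` cuts 12-TR epochs (5 on + 7 off) of the ROI-mean signal
at each onset; onsets must lie on the TR grid (true of this design; no
interpolation is attempted). `percent_change()` references each trial to
its own first TR. `time_to_peak()` takes the earliest maximum over TRs
2–12 — TR 1 is the reference and is excluded from the search; earliest-tie
breaking is deterministic and conservative. `compare_ttp()` is a two-tailed
paired t-test on per-participant mean time-to-peak.

## ROI selection

`threshold_localizer()` keeps voxels whose localizer t strictly exceeds
the criterion (default 5.09, the printed threshold corresponding to
|r| > 0.52 at the localizer's df; `localizer_t_criterion()` recomputes a
criterion from a gray-matter voxel count, which is how 5.09 arises from a
one-tail Bonferroni α = 0.05 — the exact count behind the printed value is
unreported, so the printed value is the default).
`restrict_center_dominant()` removes voxels responding more to Scotoma
than to Center (ties kept — the removal rule is strict).
`merge_rois()` implements both merge schemes: dorsal+ventral per
hemisphere for the six univariate ROIs, hemispheres combined for the three
MVPA ROIs. Retinotopic delineation itself is manual surface work and out
of scope; ROI provenance is an input label.

## MVPA

`normalize_runwise()` z-scores each voxel across each run's time points
and then min–max rescales to [0, 1]. The rescaling scope is per voxel per
run — the description "rescaled the z-scores to range 0–1" does not fix
the scope, so it is a config switch with per-voxel-per-run as the default
(it makes features invariant to any per-voxel-per-run affine transform of
the raw signal, which the tests assert). `trial_features()` averages TRs
3–7 (1-based, TR 1 = onset TR; 4–12 s after onset, bracketing the response
peak). `loro_cv()` trains a linear SVM (e1071, cost C = 1, no additional
scaling) on 7 of 8 runs (70 trials) and tests on the held-out run (10
trials), averaging the 8 fold accuracies; accuracy is raw (class balance
is ~50/50 by design), with balanced accuracy as an option.
`permutation_test()` builds the group null: each iteration freshly
permutes labels *within each run* of every participant (preserving
run-wise class counts, respecting the CV fold structure), reruns the full
cross-validation, and averages across participants; p uses the add-one
estimator `(1 + #{null ≥ obs})/(1 + n_iter)`, never zero. The study-scale
default is 5000 iterations; the calibration tests and the acceptance
script use 100–200 iterations, which already resolve p below the 0.017
threshold while keeping runtimes in minutes — a problem-size choice, not a
change of method.

## Fixation stability

`clean_gaze()` applies, in order: validity/missing-data removal, screen
bounds, and the 30°/s velocity rule (the sample *terminating* a
super-threshold movement is removed; intervals spanning a removed gap are
not velocity-tested). `bcea()` computes the bivariate contour ellipse area
`2kπσ_Hσ_V√(1−ρ²)` with probability area `1 − e^{−k}` (k = 1 ≈ 63.2%);
ellipse axes and orientation come from the covariance eigendecomposition,
and `ellipse_contains()` tests `Mahalanobis² ≤ 2k` — consistent because
`χ²₂` is Exp(1/2), which is also why the Monte Carlo containment fraction
matches `1 − e^{−k}`. `bootstrap_contrast()` resamples participants with
replacement and randomly exchanges each sampled participant's condition
pair (sign flip of the paired difference): exchangeability of conditions
within participant is the null being expressed; with n = 6 the sign-flip
null floors attainable p near 2⁻⁶ per tail, which the tests acknowledge.
`rm_anova_2()` is the two-level repeated-measures ANOVA, identically
F(1, n−1) = (paired t)². `density_map()` bins valid samples, smooths with
a separable Gaussian kernel (default bandwidth 0.1°) and max-normalizes to
[0, 1]; the upstream description of the published density maps is in
unavailable supplementary material, so this construction is the package's
own documented choice.

## Orchestration and reproducibility

`run_config()` surfaces every analysis constant (5.09, 0.0042, 0.017,
5000, 10000, 30°/s, k = 1, TR window 3–7) with the study value as default;
`run_study()` simulates the cohort and runs all stages, recording
per-stage errors without aborting downstream stages whose inputs exist.
Every random draw descends from the config seed through named substreams,
so a rerun with the same config reproduces the report bit-for-bit (the
determinism tests assert this). Readers/writers cover BIDS-style events
TSV, gaze CSV (degree and pixel dialects), ROI JSON, and the time-series
container as TSV + JSON sidecar or NIfTI via RNifti.

## Problem sizes in the test suite

The statistical acceptance checks run at sizes chosen to make the Monte
Carlo estimators well-behaved: containment and BCEA recovery at 10⁵
samples (the gaze drift reduces the effective sample count, see above);
decoding-at-chance over 50 seeds; permutation-test validity over 200 null
cohorts of 4 participants × 2 runs × 20 trials with 176 iterations (at
that iteration count the add-one p crosses the 0.017 threshold at the
third-largest null value, putting the discrete rejection rate at the
nominal level); and the dissociation recovery over 20 cohorts of 12
participants × 8 runs with the V1 pair at 40 voxels. These are the
package's simulation-size choices for calibration experiments; the
per-function defaults remain the study-scale values.

## Known limitations

* No prewhitening in the default GLM; with strong autocorrelation and
  very short runs the per-voxel t values would be anticonservative
  (group-level inference, which the pipeline actually uses, is protected
  by the between-participant variance).
* The velocity-based gaze cleaning cannot remove the interior of
  multi-sample excursions (see above).
* The SVM uses fixed C = 1 with no tuning, mirroring the analysis it
  implements; `loro_cv()` exposes the cost parameter for sensitivity
  checks but the pipeline never tunes it.
* The bootstrap's exchangeability unit (participant condition-pair) is one
  of several defensible schemes; it is a documented, configurable choice.
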