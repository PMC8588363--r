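---
title: "Cross-dataset fall detection: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-dataset fall detection: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xfall)
```

## The problem

Wearable fall detectors must distinguish the short, violent acceleration
transient of a body hitting the ground from everyday movement. Classifiers
trained on laboratory recordings of *intentional* falls often degrade when
deployed on *accidental* real-world falls, because sensor placement, gain,
noise floor and fall kinematics all shift between the two settings. This
package implements the full evaluation instrument for that question: simulate
a lab-style cohort and a shifted real-world-style event set, preprocess both
identically, train SVM / kNN / random-forest classifiers on one domain, and
measure — with confusion-matrix metrics and nonparametric tests — how much is
lost in the other.

## The synthetic-data generator

Real fall repositories are large downloads with restricted components, so the
package is testable end to end only because it ships its own generator. It
emulates two data sources:

* **Lab-style cohort** (`generate_lab_cohort()`): 23 subjects, each performing
  5 ADL archetypes and 15 fall archetypes, 5 trials each, 15 s per trial at
  200 Hz from a waist sensor. Subjects carry individual sensor orientations
  (rotations up to 12 degrees), gains (±15 %) and movement cadences, so that
  splitting by subject is meaningful.
* **Real-world-style events** (`generate_realworld_set()`): 15 continuous
  traces at 100 Hz from a lower-back sensor, each with at least 4 s of ADL
  context before one accidental fall with known impact time. The domain shift
  relative to the lab generator — per-event re-orientation, gain, extra white
  noise, baseline offset, resampling — is an explicit, tunable
  `domain_shift()` object; `identity_shift()` removes it entirely and
  `strong_shift()` (60° rotation, gain 1.5, extra noise and bias) deliberately
  breaks lab-trained models.

ADL traces keep a magnitude near 1 g (gravity) with an archetype-specific
oscillation (gait cadence 1.5–2.5 Hz for walking, up to 2.6 Hz jogging) and
never exceed 2.5 g. A fall trial follows a four-phase model (this is invented
plumbing, not a biomechanical model): ADL-like pre-fall (5.5 s), free-fall dip
to ~0.08 g (0.4 s), impact — a sharp spike reaching `impact_peak` (default
6 g) followed by ~1.2 s of broadband post-impact oscillation — then
low-variance rest.

Two generator choices deserve explanation because the impact-alignment stage
depends on them:

* Quiet-phase noise is **band-limited** (2nd-order Butterworth low-pass at
  2.5 Hz, zero-phase). Physically, body-motion and anti-aliased sensor noise
  are band-limited; statistically, smooth noise keeps the sample entropy of
  ADL and rest windows low.
* The post-impact oscillation is **white with sd 0.25 g**, confined to the
  impact window. Sample entropy with a tolerance proportional to the window's
  own standard deviation is scale-invariant, so what separates the impact
  window is not the spike's amplitude but the *irregularity* of the crash
  transient at the window's dominant scale. With these defaults the impact
  window's SampEn (≥ ~0.45 across seeds) exceeds every ADL/rest window
  (≤ ~0.25) by a wide margin — measured over seeded traces before the
  defaults were frozen.

What the generator does **not** emulate: realistic fall biomechanics (the 15
fall archetypes differ only by parameter presets — context activity and peak
scale — because no generative kinematic model is available), gyroscopes,
multi-fall traces, soft falls with sub-2 g impacts, or non-stationary daily
routines. Passing tests therefore demonstrate that the *pipeline logic* is
correct and sensitive to domain shift, not that the trained models would
perform at any particular level on real recordings.

## Preprocessing

Traces are epoched into fixed windows (default 500 samples = 2.5 s at 200 Hz)
with 0 % or 50 % overlap; trailing partial windows are dropped. Window
indexing is 0-based and half-open, `[start, start + W)`.

**Impact alignment.** Fall trials contain one short event surrounded by
unrelated movement, so the FALL-labeled window must be located. Sample
entropy, `SampEn = -ln(A/B)` with template matches counted under a Chebyshev
tolerance, is computed per window and the maximal window above a threshold is
kept; all other windows of a fall trial are *discarded*, not labeled ADL,
because pre- and post-fall transients are neither clean ADL nor falls.
Parameters: `m = 2`, `r = 0.2 × window SD`, computed on the Euclidean
magnitude channel — field-standard defaults, exposed in `sampen_params()`.
When no template of length `m + 1` matches (A = 0), SampEn is undefined; the
package treats that window as maximally irregular, which is the conservative
choice for event localization. The threshold is calibrated on the cohort as
the midpoint between the largest ADL-window SampEn and the smallest per-trial
maximal SampEn (`calibrate_threshold()`), and calibration fails loudly if the
two ranges overlap.

**Real-world labeling.** Events with a known impact time use the fixed
convention: the 4 s ending 1.5 s before the impact is ADL; the 2.5 s spanning
1.5 s before to 1.0 s after the impact is the FALL segment (always 2.5 s,
independent of the lab window length). The ADL context is epoched into
window-sized sub-windows, falling back to 50 % overlap only if a full window
would not fit otherwise. Real-world traces are resampled to the lab rate
before feature extraction with a polyphase FIR resampler written for this
package (Kaiser-windowed linear-phase design, delay-compensated; the signal
mean bypasses the filter so constants survive exactly).

## Features and standardization

Each window yields 36 features: {mean, median, sd, variance, min, max, 0.25
and 0.75 quantile, normalized spectral entropy} × {x, y, z, s}. The summation
channel is read literally as `s(t) = |ax| + |ay| + |az|`; a Euclidean-norm
alternative sits behind `summation_channel(method = "euclidean")` since both
conventions are common. Spectral entropy normalizes the Shannon entropy of
the one-sided power spectrum by `log(n_bins)` with the DC bin included, so a
constant window scores 0 and white noise approaches 1; whether DC should be
excluded is a genuinely open choice, and including it is what makes constant
windows well-defined. Variance uses the sample (n−1) convention; quantiles
use linear interpolation.

Standardization (mean 0, sd 1 per feature) is always computed on the training
rows and **reused frozen** for the lab test set and the real-world set; a
feature constant in training is left centred with sd treated as 1 (columns of
zeros) with a warning, never NaN.

## Model selection

Three families are supported through their standard R implementations
(`e1071::svm` with a linear kernel, `class::knn`, `randomForest`); this
package owns what matters scientifically — subject-grouped resampling,
selection, tuning and the frozen-parameter contract. One mapping is
approximate: the "maximum number of levels" cap is expressed through
`randomForest`'s terminal-node budget (`maxnodes`), the closest control the
backend offers. The kNN distance is Euclidean only. When `min_leaf` reaches
the training-set size no split can respect it, and the forest collapses to
the majority class explicitly.

**Sequential backward selection** starts from all 36 features and repeatedly
removes the feature whose removal maximizes 5-fold subject-grouped
cross-validated accuracy under the family's default hyperparameters, stopping
when the best removal no longer improves the score by more than `tolerance`
(default 0, i.e. strict improvement required). Ties between candidate
removals drop the highest index, so the lowest-indexed of two equivalent
features survives. Selection runs *before* grid search because the protocol
orders a feature-selection phase first and leaves the selection scorer
unspecified; defaults are the natural choice and both knobs are exposed.

**Grid search** then evaluates the family's grid exhaustively with the same
grouped CV: SVM `C` log-spaced in [0.01, 10], kNN `k` in 1..10, RF
`max_split_features` in [1, 17], `max_levels` in [30, 80], `min_leaf` in
[1, 48]. Rows are visited simplest-first (smaller `C`, larger `k`, smaller
`max_levels`), so score ties resolve toward the simpler model. Continuous
ranges use 7 log-spaced points by default; the resolution is a config knob
because the protocol gives bounds, not step counts.

## The evaluation workflow

`run_workflow()` executes, for each trial index `t` (only the `t`-th
recording of each activity participates — the reading of "trained separately
for each of the five trials" that keeps runs independent) and each of
`n_repetitions` random draws: hold out `n_test_subjects` whole subjects;
select features, tune and train on the remaining subjects; evaluate on the
held-out lab subjects *and* on the entire real-world set (never split) with
frozen hyperparameters and training standardization. Metrics are accuracy,
sensitivity (`TP/(TP+FN)`) and specificity (`TN/(TN+FP)`), with FALL the
positive class; confusion counts are pooled over real-world events before
metrics are computed. Undefined metrics (zero denominators) are excluded from
aggregation and counted, not imputed. Every run records its split seed and a
provenance entry (hyperparameters, feature subset, standardization vectors,
subject sets), which the audit tests replay. The whole loop runs inside a
seeded RNG scope, so reports are bit-reproducible.

`compare_classifiers()` applies a Kruskal–Wallis test across families on the
per-run metric and, when significant at `alpha = 0.05`, all pairwise
Mann–Whitney U tests with Bonferroni-adjusted alpha, reporting raw and
adjusted decisions. `generalization_gap()` contrasts in-domain and
cross-domain runs per family. `window_length_sweep()` reruns the SVM workflow
at 250/500/750-sample epochs.

## Numerical and degenerate-input choices

* SampEn uses the first `n − m` templates for both template lengths and
  excludes self-matches; a constant series returns 0 (tolerance collapses but
  the match ratio is 1 by convention).
* The threshold calibration is a hard midpoint, not a quantile: with the
  generator's separation margin a midpoint is unambiguous, and an overlap is
  reported as a failure with both boundary values rather than silently
  producing a poor threshold.
* Resampling output length is `round(n · target/rate)`; edge effects are
  confined to well under 1 % of a trace at the default filter length.
* All randomness flows through explicit integer seeds; generator functions
  restore the caller's RNG state.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run desk-scale versions of the
study: alignment recovery over 200 seeded fall traces, and a cross-dataset
experiment with 10 subjects × 2 trials, 3 repetitions, 3 held-out subjects,
3-fold grouped CV and 3-point continuous grids, against 15 strongly shifted
real-world events. These sizes were chosen so the full study runs in minutes
on one core while keeping every structural property of the full protocol (a
23-subject × 5-trial cohort simply scales the same code).

## Known limitations

* The generator's separability is deliberate: impact peaks (≥ 5 g) clear ADL
  peaks (≤ 2.5 g), so a 3 g magnitude threshold is a perfect oracle and
  in-domain classification is near-ceiling. Real datasets are harder; results
  on synthetic data bound the pipeline's correctness, not field performance.
* Which classifier family degrades most under shift depends on the shift's
  geometry; the package guarantees the *instrument* (a detectable,
  statistically tested gap under `strong_shift()`), not a particular ranking.
* FARSEEING's native export format is not parsed; real-world-style data enter
  via the generic CSV/manifest route.
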