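# xfall — cross-dataset fall detection from tri-axial accelerometry

Falls are among the most dangerous events detectable from a waist- or
back-worn accelerometer, and classifiers that look excellent on laboratory
recordings of *intentional* falls routinely degrade on *accidental*,
real-world ones: sensor placement, gain, noise floor and fall kinematics all
shift between domains. `xfall` is an R package for quantifying exactly that
gap. It is written for researchers in wearable-sensor digital health and
human activity recognition who need a tested, reproducible version of the
full cross-dataset evaluation protocol — from raw tri-axial traces to
nonparametric classifier comparisons — without depending on restricted
downloads.

## What the package does

1. **Simulates both domains.** `generate_lab_cohort()` builds a lab-style
   cohort (default: 23 subjects × (5 ADL + 15 fall archetypes) × 5 trials,
   15 s at 200 Hz, per-subject sensor orientation and gain), and
   `generate_realworld_set()` builds continuous real-world-style events
   (default: 15 falls at 100 Hz with ≥ 4 s of ADL context) passed through an
   explicit `domain_shift()` (rotation, gain, noise, bias, resampling).
2. **Reads and writes the field's formats.** SisFall-dialect delimited text
   (9 integer columns, ADC counts at ±16 g / 13 bit by default) with a
   `manifest.csv` sidecar, generic `ax,ay,az` CSV, and polyphase FIR
   resampling between rates (`resample_trace()`).
3. **Aligns fall impacts with sample entropy.** Trials known to contain one
   fall are epoched (default 2.5 s windows) and the window maximizing

   `SampEn = -ln(A/B)`,

   with A/B the counts of Chebyshev-matching templates of length m+1 and m
   (m = 2, tolerance r = 0.2 × window SD, magnitude channel), is kept as the
   FALL segment above a cohort-calibrated threshold
   (`calibrate_threshold()`, `locate_fall_window()`). Real-world events with
   known impact time use the fixed convention: 4 s of ADL ending 1.5 s
   before the impact, and a FALL segment spanning [impact − 1.5 s,
   impact + 1.0 s).
4. **Extracts 36 features per window** — {mean, median, sd, var, min, max,
   q25, q75, spectral entropy} × {x, y, z, s(t) = |ax|+|ay|+|az|} — and
   standardizes every evaluation set with frozen training statistics.
5. **Trains and tunes classifiers.** `fall_classifier()` fits a linear SVM,
   kNN or random forest; `sequential_backward_selection()` and
   `grid_search()` run subject-grouped cross-validated feature selection and
   hyperparameter tuning (SVM C ∈ [0.01, 10], kNN k ∈ [1, 10], RF
   split-features ∈ [1, 17], levels ∈ [30, 80], leaf ∈ [1, 48]).
6. **Measures generalization.** `run_workflow()` repeats the subject-wise
   protocol (hold out 6 of 23 subjects, 10 repetitions, each of 5 trials in
   turn, by default), evaluating each frozen model on the lab test set and
   on the entire real-world set with accuracy, sensitivity = TP/(TP+FN) and
   specificity = TN/(TN+FP). `compare_classifiers()` applies Kruskal–Wallis
   plus Bonferroni-corrected Mann–Whitney post hoc tests;
   `generalization_gap()` tests the in- vs cross-domain drop per family;
   `window_length_sweep()` probes 250/500/750-sample epochs.

## Worked example

A scaled-down study: 8 simulated subjects, 2 trials, three repetitions of a
2-subject hold-out, and 15 real-world events under a strong domain shift
(60° re-orientation, gain 1.5, extra noise):

```r
library(xfall)
lab <- generate_lab_cohort(cohort_spec(n_subjects = 8,
                                       n_trials_per_activity = 2, seed = 1))
rw  <- generate_realworld_set(15, strong_shift(), seed = 2)
cfg <- experiment_config(n_test_subjects = 2, n_repetitions = 3, n_trials = 2,
                         seed = 3, grid_points = 3, folds = 3)
ex <- run_workflow(lab, rw, cfg)
print(ex)
#> <fall_experiment> 18 runs (2 trials x 3 repetitions x 3 classifiers), SampEn threshold 0.290
#>  classifier  eval_set value.accuracy value.sensitivity value.specificity
#>         svm  lab_test  1.00 +/- 0.00     1.00 +/- 0.00     1.00 +/- 0.00
#>         svm realworld  0.61 +/- 0.06     0.21 +/- 0.12     1.00 +/- 0.00
#>         knn  lab_test  1.00 +/- 0.00     1.00 +/- 0.00     1.00 +/- 0.00
#>         knn realworld  0.57 +/- 0.00     0.13 +/- 0.00     1.00 +/- 0.00
#>          rf  lab_test  1.00 +/- 0.00     1.00 +/- 0.00     1.00 +/- 0.00
#>          rf realworld  0.89 +/- 0.09     0.79 +/- 0.19     1.00 +/- 0.00
```

Every family is perfect in-domain (the synthetic study is
separable-by-design, so this matches the 3 g magnitude-threshold oracle);
under the injected shift, cross-domain sensitivity collapses for SVM and kNN
while the random forest holds up — and the drop is statistically detectable:

```r
generalization_gap(ex, "accuracy")
#>   classifier median_in_domain median_cross_domain      p_value drop
#> 1        svm                1           0.5666667 0.0016901019 TRUE
#> 2        knn                1           0.5666667 0.0009111189 TRUE
#> 3         rf                1           0.8833333 0.0222296182 TRUE

compare_classifiers(ex, "accuracy", "realworld")
#> Kruskal-Wallis on accuracy (realworld): H = 14.227, p = 0.0008142 (alpha = 0.05)
#> post hoc Mann-Whitney U (Bonferroni):
#>  group1 group2  U       p_raw alpha_bonferroni significant_raw significant_adjusted ...
#>     knn     rf  0 0.002724532       0.01666667            TRUE                 TRUE
#>     knn    svm 12 0.175734336       0.01666667           FALSE                FALSE
#>      rf    svm 36 0.004266725       0.01666667            TRUE                 TRUE
```

Which family degrades most depends on the geometry of the injected shift;
the package guarantees the measuring instrument, not a particular ranking
(see the methods vignette, `vignettes/fall-detection-pipeline.Rmd`).

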