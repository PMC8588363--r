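test_that("metrics follow the confusion-count formulae exactly", {
  m <- compute_metrics(c(TP = 14, FN = 1, TN = 0, FP = 0))
  expect_equal(unname(m["sensitivity"]), 14 / 15)
  expect_true(is.na(m["specificity"]))  # undefined denominator
  expect_equal(compute_metrics(c(TP = 5, TN = 5, FP = 0, FN = 0)),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  expect_equal(unname(compute_metrics(c(TP = 25, TN = 25, FP = 25, FN = 25))),
               c(0.5, 0.5, 0.5))
  expect_error(compute_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)),
               class = "xfall_invalid_argument")
  expect_error(compute_metrics(c(TP = -1, TN = 2, FP = 1, FN = 1)),
               class = "xfall_invalid_argument")

  # 100 random confusion tables against direct arithmetic
  set.seed(10)
  for (i in 1:100) {
    cc <- c(TP = rpois(1, 20), TN = rpois(1, 20), FP = rpois(1, 5),
            FN = rpois(1, 5)) + c(1, 1, 0, 0)
    m <- compute_metrics(cc)
    expect_identical(unname(m["accuracy"]),
                     (cc[["TP"]] + cc[["TN"]]) / sum(cc))
    expect_identical(unname(m["sensitivity"]), cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]))
    expect_identical(unname(m["specificity"]), cc[["TN"]] / (cc[["TN"]] + cc[["FP"]]))
  }
})

test_that("confusion counting treats FALL as the positive class", {
  truth <- c("FALL", "FALL", "ADL", "ADL", "ADL")
  pred <- c("FALL", "ADL", "FALL", "ADL", "ADL")
  expect_identical(confusion_counts(truth, pred),
                   c(TP = 1L, TN = 2L, FP = 1L, FN = 1L))
})

test_that("classifier comparison runs omnibus and Bonferroni post hoc tests", {
  mk_runs <- function(vals, fams) {
    do.call(rbind, lapply(seq_along(fams), function(i)
      data.frame(classifier = fams[i], eval_set = "lab_test",
                 accuracy = vals[[i]])))
  }
  # identical distributions: no significance, no post hoc
  same <- mk_runs(list(c(.9, .91, .92, .9), c(.9, .91, .92, .9),
                       c(.9, .91, .92, .9)), c("svm", "knn", "rf"))
  cmp <- compare_classifiers(same, "accuracy", "lab_test")
  expect_true(is.na(cmp$p_value) || cmp$p_value > 0.05)
  expect_null(cmp$posthoc)

  # planted dominance: svm shifted above the others
  set.seed(8)
  shifted <- mk_runs(list(rnorm(50, .95, .01), rnorm(50, .80, .03),
                          rnorm(50, .80, .03)), c("svm", "knn", "rf"))
  cmp2 <- compare_classifiers(shifted, "accuracy", "lab_test")
  expect_lt(cmp2$p_value, 0.05)
  expect_s3_class(cmp2$posthoc, "data.frame")
  svm_rows <- cmp2$posthoc[cmp2$posthoc$group1 == "svm" | cmp2$posthoc$group2 == "svm", ]
  expect_equal(nrow(svm_rows), 2L)
  expect_true(all(svm_rows$significant_adjusted))
  win <- ifelse(svm_rows$group1 == "svm", svm_rows$median1 > svm_rows$median2,
                svm_rows$median2 > svm_rows$median1)
  expect_true(all(win))
  expect_equal(unique(cmp2$posthoc$alpha_bonferroni), 0.05 / 3)

  # two classifiers only: Bonferroni divisor is one pair
  two <- mk_runs(list(rnorm(30, .95, .01), rnorm(30, .7, .03)), c("svm", "knn"))
  cmp3 <- compare_classifiers(two, "accuracy", "lab_test")
  expect_equal(cmp3$posthoc$alpha_bonferroni, 0.05)

  # constant tied samples: undefined marker, not a crash
  const <- mk_runs(list(rep(1, 4), rep(1, 4), rep(1, 4)), c("svm", "knn", "rf"))
  expect_true(is.na(compare_classifiers(const, "accuracy", "lab_test")$p_value))
  expect_error(compare_classifiers(same[same$classifier == "svm", ], "accuracy",
                                   "lab_test"),
               class = "xfall_invalid_argument")
})

# A miniature end-to-end experiment shared by the workflow assertions.
mini_experiment <- local({
  cat2 <- activity_catalog(fall_types = sisfall_fall_types()[1:3],
                           adl_types = sisfall_adl_types()[1:2])
  lab <- generate_lab_cohort(cohort_spec(n_subjects = 5,
                                         n_trials_per_activity = 2, seed = 31),
                             cat2)
  rw <- generate_realworld_set(5, seed = 32)
  cfg <- experiment_config(n_test_subjects = 2, n_repetitions = 2, n_trials = 2,
                           seed = 33, families = c("svm", "knn"), sbs = FALSE,
                           grid_points = 2, folds = 3)
  list(lab = lab, rw = rw, cfg = cfg, ex = run_workflow(lab, rw, cfg))
})

test_that("the workflow produces the full run grid with disjoint subject splits", {
  ex <- mini_experiment$ex
  cfg <- mini_experiment$cfg
  # trials x repetitions x classifiers x eval sets
  expect_equal(nrow(ex$runs), 2 * 2 * 2 * 2)
  expect_setequal(unique(ex$runs$eval_set), c("lab_test", "realworld"))
  counts <- table(ex$runs$classifier, ex$runs$eval_set)
  expect_true(all(counts == cfg$n_repetitions * cfg$n_trials))
  # no subject leakage in any repetition
  for (p in ex$provenance) {
    expect_length(p$test_subjects, cfg$n_test_subjects)
    expect_length(intersect(p$train_subjects, p$test_subjects), 0L)
  }
  # the real-world set is never split: every realworld row saw all 5 events
  rw_rows <- ex$runs[ex$runs$eval_set == "realworld", ]
  n_rw_segments <- rw_rows$TP + rw_rows$TN + rw_rows$FP + rw_rows$FN
  expect_true(all(n_rw_segments == n_rw_segments[1]))
  expect_gte(n_rw_segments[1], 10)  # >= one ADL + one FALL window per event
})

test_that("cross-domain rows reuse the frozen model of their lab-test twin", {
  ex <- mini_experiment$ex
  runs <- ex$runs
  key <- paste(runs$classifier, runs$trial, runs$repetition)
  for (k in unique(key)) {
    pair <- runs[key == k, ]
    expect_equal(nrow(pair), 2L)
    # same provenance entry: same hyperparameters, standardization, features
    expect_identical(unique(pair$provenance_id), pair$provenance_id[1])
  }
  for (p in ex$provenance) {
    expect_length(p$center, 36L)
    expect_length(p$scale, 36L)
    expect_gt(length(p$selected_features), 0L)
  }
})

test_that("workflow runs are seed-reproducible", {
  ex2 <- run_workflow(mini_experiment$lab, mini_experiment$rw,
                      mini_experiment$cfg)
  expect_equal(ex2$runs, mini_experiment$ex$runs)
  expect_equal(ex2$threshold, mini_experiment$ex$threshold)
})

test_that("experiment reports print, summarize and compare", {
  ex <- mini_experiment$ex
  expect_output(print(ex), "fall_experiment")
  s <- summary(ex)
  expect_true(all(c("classifier", "eval_set", "metric", "mean", "sd") %in% names(s)))
  expect_true(all(s$mean[!is.na(s$mean)] >= 0 & s$mean[!is.na(s$mean)] <= 1))
  gap <- generalization_gap(ex)
  expect_setequal(gap$classifier, c("svm", "knn"))
  expect_true(all(c("median_in_domain", "median_cross_domain", "p_value", "drop")
                  %in% names(gap)))
})

test_that("the window-length sweep reruns the SVM workflow per length", {
  cfg <- experiment_config(n_test_subjects = 2, n_repetitions = 1, n_trials = 1,
                           seed = 41, sbs = FALSE, grid_points = 2, folds = 3)
  sw <- window_length_sweep(mini_experiment$lab, mini_experiment$rw,
                            lengths = c(250, 500), cfg)
  expect_named(sw, c("W250", "W500"))
  # 250 samples at 200 Hz = 1.25 s epochs; 500 = 2.5 s
  expect_equal(sw$W250$config$window_samples / 200, 1.25)
  expect_equal(sw$W500$config$window_samples / 200, 2.5)
  expect_true(all(sw$W250$runs$classifier == "svm"))
  expect_identical(names(sw$W250$runs), names(sw$W500$runs))
  expect_error(window_length_sweep(mini_experiment$lab, mini_experiment$rw,
                                   lengths = c(1, 500), cfg),
               class = "xfall_invalid_argument")
})
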