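#' Confusion counts for fall detection
#'
#' FALL is the positive class: TP = correctly detected fall, TN = correctly
#' detected ADL, FP = ADL labeled as fall, FN = missed fall.
#'
#' @param truth,pred factors/characters with values in ADL, FALL.
#' @return named integer vector (TP, TN, FP, FN).
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  c(TP = sum(truth == "FALL" & pred == "FALL"),
    TN = sum(truth == "ADL" & pred == "ADL"),
    FP = sum(truth == "ADL" & pred == "FALL"),
    FN = sum(truth == "FALL" & pred == "ADL"))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). A metric whose denominator is zero is returned
#' as `NA` (undefined marker); all-zero counts are an error.
#'
#' @param counts named vector with TP, TN, FP, FN (all >= 0).
#' @return named numeric vector (accuracy, sensitivity, specificity).
#' @export
compute_metrics <- function(counts) {
  counts <- counts[c("TP", "TN", "FP", "FN")]
  if (any(is.na(counts)) || any(counts < 0))
    xf_stop("counts must be non-negative", "invalid_argument")
  if (sum(counts) == 0) xf_stop("all-zero confusion counts", "invalid_argument")
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  div <- function(a, b) if (b > 0) a / b else NA_real_
  c(accuracy = div(tp + tn, tp + tn + fp + fn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp))
}

#' Magnitude-threshold oracle labels
#'
#' Labels a window FALL when its peak Euclidean magnitude exceeds `threshold`
#' (default 3 g). With separable generator settings (impact peaks >= 5 g, ADL
#' peaks <= 2.5 g) this oracle is perfect and lower-bounds what a trained
#' classifier should achieve in-domain.
#'
#' @param segments list of [accel_segment()]s.
#' @param threshold in g.
#' @return factor of labels (ADL/FALL).
#' @export
magnitude_threshold_oracle <- function(segments, threshold = 3) {
  factor(vapply(segments, function(s)
    if (max(magnitude(s$samples)) > threshold) "FALL" else "ADL", character(1)),
    levels = c("ADL", "FALL"))
}

#' Experiment configuration
#'
#' Defaults mirror the repeated subject-wise protocol: 6 of the 23 subjects
#' held out, 10 repetitions, each of the 5 trials used in turn, 2.5 s windows
#' (500 samples at 200 Hz), non-overlapping.
#'
#' @param n_test_subjects held-out subjects per repetition.
#' @param n_repetitions random re-draws of the held-out set per trial.
#' @param n_trials trial indices used in turn (trial t trains/tests on the
#'   t-th recording of every activity).
#' @param window_samples epoch length in samples.
#' @param overlap 0 or 0.5.
#' @param seed master seed; all per-repetition splits derive from it and are
#'   recorded in the report for replay.
#' @param families classifier families to run.
#' @param sampen a [sampen_params()].
#' @param folds grouped CV folds for selection/tuning.
#' @param sbs run sequential backward selection (logical).
#' @param sbs_tolerance SBS stopping tolerance.
#' @param grid_points grid resolution per continuous hyperparameter range.
#' @export
experiment_config <- function(n_test_subjects = 6, n_repetitions = 10,
                              n_trials = 5, window_samples = 500, overlap = 0,
                              seed = 1, families = c("svm", "knn", "rf"),
                              sampen = sampen_params(), folds = 5, sbs = TRUE,
                              sbs_tolerance = 0, grid_points = 7) {
  structure(list(n_test_subjects = as.integer(n_test_subjects),
                 n_repetitions = as.integer(n_repetitions),
                 n_trials = as.integer(n_trials),
                 window_samples = as.integer(window_samples),
                 overlap = overlap, seed = seed, families = families,
                 sampen = sampen, folds = folds, sbs = sbs,
                 sbs_tolerance = sbs_tolerance, grid_points = grid_points),
            class = "experiment_config")
}

## internal: impact-align fall trials and epoch ADL trials of a lab dataset
## into a labeled feature matrix. Fall trials contribute exactly one aligned
## FALL segment; their remaining windows are discarded.
lab_feature_matrix <- function(lab, config, threshold) {
  man <- lab$manifest
  segs <- list(); subj <- character(0); trial <- integer(0); dropped <- 0L
  for (i in seq_along(lab$traces)) {
    tr <- lab$traces[[i]]
    if (man$label[i] == "FALL") {
      res <- tryCatch(
        locate_fall_window(tr, config$window_samples, config$sampen, threshold,
                           config$overlap),
        xfall_no_event_found = function(e) NULL)
      if (is.null(res)) { dropped <- dropped + 1L; next }
      new <- list(res$segment)
    } else {
      new <- epoch(tr, config$window_samples, config$overlap, label = "ADL")
    }
    segs <- c(segs, new)
    subj <- c(subj, rep(man$subject[i], length(new)))
    trial <- c(trial, rep(man$trial[i], length(new)))
  }
  fm <- extract_feature_matrix(segs, subject_ids = subj, trial = trial)
  attr(fm, "dropped_fall_trials") <- dropped
  attr(fm, "segments") <- segs
  fm
}

## internal: fixed-convention labeling of the real-world set at the lab rate
realworld_feature_matrix <- function(rw, config, lab_rate) {
  window_seconds <- config$window_samples / lab_rate
  segs <- list(); subj <- character(0)
  for (i in seq_along(rw$traces)) {
    tr <- rw$traces[[i]]
    if (tr$rate != lab_rate) tr <- resample_trace(tr, lab_rate)
    new <- label_realworld(tr, window_seconds = window_seconds)
    segs <- c(segs, new)
    subj <- c(subj, rep(rw$manifest$subject[i], length(new)))
  }
  fm <- extract_feature_matrix(segs, subject_ids = subj,
                               trial = rep(1L, length(segs)))
  attr(fm, "segments") <- segs
  fm
}

#' Run the repeated subject-wise cross-dataset workflow
#'
#' Implements the five-step protocol: (1) randomly hold out
#' `n_test_subjects` whole subjects from the lab cohort, (2) feature
#' selection, grid search and training on the remaining subjects only,
#' (3) evaluation on the lab test set AND on the entire real-world set with
#' frozen hyperparameters and training-set standardization, (4) repeated
#' `n_repetitions` times, (5) for each of the `n_trials` trial indices in
#' turn (trial t uses only the t-th recording of each activity). Fall trials
#' are impact-aligned with a SampEn threshold calibrated on the lab cohort
#' beforehand; the real-world set is labeled by its known impact times and is
#' never split.
#'
#' @param lab an `accel_dataset` from [generate_lab_cohort()] (or
#'   [read_dataset()]).
#' @param realworld an `accel_dataset` of real-world-style events with known
#'   impact times.
#' @param config an [experiment_config()].
#' @return object of class `fall_experiment`: `runs` (one row per classifier
#'   x trial x repetition x eval set with confusion counts and metrics),
#'   `summary` (mean +/- sd), `provenance`, `threshold`, `config`.
#' @export
run_workflow <- function(lab, realworld, config = experiment_config()) {
  man <- lab$manifest
  subjects <- sort(unique(man$subject))
  if (length(subjects) < config$n_test_subjects + 2L)
    xf_stop("cohort must have at least n_test_subjects + 2 subjects",
            "invalid_argument")
  if (max(man$trial) < config$n_trials)
    xf_stop("cohort has fewer trials than config$n_trials", "invalid_argument")

  fall_traces <- lab$traces[man$label == "FALL"]
  adl_traces <- lab$traces[man$label == "ADL"]
  threshold <- calibrate_threshold(fall_traces, adl_traces,
                                   config$window_samples, config$sampen,
                                   config$overlap)
  lab_fm <- lab_feature_matrix(lab, config, threshold)
  rw_fm <- realworld_feature_matrix(realworld, config, man$rate[1])

  ## the whole training/evaluation loop runs under a seeded RNG scope so that
  ## reports are bit-reproducible (nearest-neighbour tie-breaking and forest
  ## bootstraps draw from this stream)
  with_seed(config$seed, {
  split_seeds <- matrix(draw_seeds(config$n_trials * config$n_repetitions),
                        config$n_trials, config$n_repetitions)
  runs <- list(); prov <- list(); undefined <- 0L
  for (t in seq_len(config$n_trials)) {
    for (rep_i in seq_len(config$n_repetitions)) {
      s <- split_seeds[t, rep_i]
      test_subj <- with_seed(s, sample(subjects, config$n_test_subjects))
      in_trial <- lab_fm$trial == t
      tr_rows <- in_trial & !(lab_fm$subject_ids %in% test_subj)
      te_rows <- in_trial & (lab_fm$subject_ids %in% test_subj)
      train <- feature_matrix(lab_fm$x[tr_rows, , drop = FALSE],
                              lab_fm$labels[tr_rows],
                              lab_fm$subject_ids[tr_rows])
      test <- feature_matrix(lab_fm$x[te_rows, , drop = FALSE],
                             lab_fm$labels[te_rows],
                             lab_fm$subject_ids[te_rows])
      std <- standardize(train, list(test, rw_fm))
      for (fam in config$families) {
        sel <- if (config$sbs)
          sequential_backward_selection(std$train, fam, folds = config$folds,
                                        tolerance = config$sbs_tolerance,
                                        seed = s)
        else seq_len(ncol(std$train$x))
        sub_train <- std$train
        sub_train$x <- sub_train$x[, sel, drop = FALSE]
        spec <- grid_search(sub_train, fam,
                            grid = hyperparam_grid(fam, config$grid_points),
                            folds = config$folds, seed = s)
        model <- fall_classifier(std$train, fam,
                                 hyperparams = spec$hyperparams,
                                 selected_features = sel, seed = s)
        pid <- sprintf("t%d_r%d_%s", t, rep_i, fam)
        prov[[pid]] <- list(hyperparams = model$spec$hyperparams,
                            selected_features = sel,
                            center = std$center, scale = std$scale,
                            train_subjects = sort(unique(train$subject_ids)),
                            test_subjects = sort(test_subj), seed = s)
        for (es in c("lab_test", "realworld")) {
          fm_eval <- if (es == "lab_test") std$others[[1]] else std$others[[2]]
          cc <- confusion_counts(fm_eval$labels, predict(model, fm_eval))
          met <- compute_metrics(cc)
          undefined <- undefined + sum(is.na(met))
          runs[[length(runs) + 1L]] <- data.frame(
            classifier = fam, trial = t, repetition = rep_i, eval_set = es,
            TP = cc[["TP"]], TN = cc[["TN"]], FP = cc[["FP"]], FN = cc[["FN"]],
            accuracy = met[["accuracy"]], sensitivity = met[["sensitivity"]],
            specificity = met[["specificity"]], n_features = length(sel),
            split_seed = s, provenance_id = pid)
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  structure(list(runs = runs, summary = summarize_runs(runs),
                 provenance = prov, threshold = threshold, config = config,
                 n_undefined_metrics = undefined,
                 dropped_fall_trials = attr(lab_fm, "dropped_fall_trials")),
            class = "fall_experiment")
  })
}

## internal: mean +/- sd per classifier, eval set and metric; undefined
## metrics are excluded from aggregation, with a count.
summarize_runs <- function(runs) {
  out <- list()
  for (fam in unique(runs$classifier)) for (es in unique(runs$eval_set)) {
    sub <- runs[runs$classifier == fam & runs$eval_set == es, ]
    for (mt in c("accuracy", "sensitivity", "specificity")) {
      v <- sub[[mt]]
      out[[length(out) + 1L]] <- data.frame(
        classifier = fam, eval_set = es, metric = mt,
        mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
        n = sum(!is.na(v)), n_undefined = sum(is.na(v)))
    }
  }
  do.call(rbind, out)
}

#' @export
print.fall_experiment <- function(x, ...) {
  cat(sprintf("<fall_experiment> %d runs (%d trials x %d repetitions x %d classifiers), SampEn threshold %.3f\n",
              nrow(x$runs) / 2, x$config$n_trials, x$config$n_repetitions,
              length(x$config$families), x$threshold))
  s <- x$summary
  s$value <- sprintf("%.2f +/- %.2f", s$mean, s$sd)
  print(stats::reshape(s[, c("classifier", "eval_set", "metric", "value")],
                       idvar = c("classifier", "eval_set"),
                       timevar = "metric", direction = "wide"),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.fall_experiment <- function(object, ...) object$summary

#' @export
plot.fall_experiment <- function(x, y = "accuracy", ...) {
  metric <- y
  graphics::boxplot(stats::as.formula(paste(metric, "~ classifier + eval_set")),
                    data = x$runs, las = 2, ylab = metric,
                    main = "fall detection performance", ...)
  invisible(x)
}

#' Nonparametric comparison of classifier families
#'
#' Kruskal-Wallis test across families on the per-run metric; when p < alpha,
#' all pairwise Mann-Whitney U tests are run as post hoc tests with
#' Bonferroni correction (adjusted alpha = alpha / number of pairs), and both
#' the raw and the adjusted decisions are reported. Constant tied samples
#' yield an undefined-marker (`NA`) p-value rather than an error.
#'
#' @param experiment a `fall_experiment` (or its `runs` data.frame).
#' @param metric `"accuracy"`, `"sensitivity"` or `"specificity"`.
#' @param eval_set `"lab_test"` or `"realworld"`.
#' @param alpha significance level.
#' @return list (class `classifier_comparison`): `test`, `statistic`,
#'   `p_value`, `alpha`, `posthoc` (data.frame or NULL).
#' @export
compare_classifiers <- function(experiment, metric = "accuracy",
                                eval_set = "lab_test", alpha = 0.05) {
  runs <- if (inherits(experiment, "fall_experiment")) experiment$runs else experiment
  sub <- runs[runs$eval_set == eval_set & !is.na(runs[[metric]]), ]
  fams <- unique(sub$classifier)
  if (length(fams) < 2L) xf_stop("need >= 2 classifiers", "invalid_argument")
  if (any(table(sub$classifier) < 2L))
    xf_stop("need >= 2 runs per classifier", "invalid_argument")
  v <- sub[[metric]]; g <- factor(sub$classifier)
  kw <- if (stats::var(v) == 0) list(statistic = NA_real_, p.value = NA_real_)
        else stats::kruskal.test(v, g)
  res <- list(test = "kruskal-wallis", metric = metric, eval_set = eval_set,
              statistic = unname(kw$statistic), p_value = kw$p.value,
              alpha = alpha, posthoc = NULL)
  if (!is.na(res$p_value) && res$p_value < alpha) {
    pairs <- utils::combn(sort(fams), 2)
    n_pairs <- ncol(pairs)
    ph <- lapply(seq_len(n_pairs), function(i) {
      a <- v[g == pairs[1, i]]; b <- v[g == pairs[2, i]]
      mw <- if (stats::var(c(a, b)) == 0) list(statistic = NA_real_, p.value = NA_real_)
            else suppressWarnings(stats::wilcox.test(a, b))
      data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
                 U = unname(mw$statistic), p_raw = mw$p.value,
                 alpha_bonferroni = alpha / n_pairs,
                 significant_raw = !is.na(mw$p.value) && mw$p.value < alpha,
                 significant_adjusted = !is.na(mw$p.value) &&
                   mw$p.value < alpha / n_pairs,
                 median1 = stats::median(a), median2 = stats::median(b))
    })
    res$posthoc <- do.call(rbind, ph)
  }
  structure(res, class = "classifier_comparison")
}

#' @export
print.classifier_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on %s (%s): H = %.3f, p = %.4g (alpha = %g)\n",
              x$metric, x$eval_set, x$statistic, x$p_value, x$alpha))
  if (!is.null(x$posthoc)) {
    cat("post hoc Mann-Whitney U (Bonferroni):\n")
    print(x$posthoc, row.names = FALSE)
  } else cat("no post hoc tests (omnibus not significant)\n")
  invisible(x)
}

#' Per-family in-domain vs cross-domain performance gap
#'
#' For each classifier family, compares the per-run metric between the lab
#' test set and the real-world set (Kruskal-Wallis with two groups, i.e. a
#' Mann-Whitney-type rank test) and reports whether cross-domain performance
#' dropped.
#'
#' @param experiment a `fall_experiment`.
#' @param metric metric name.
#' @return data.frame with medians, p-value and drop indicator per family.
#' @export
generalization_gap <- function(experiment, metric = "accuracy") {
  runs <- experiment$runs
  out <- lapply(unique(runs$classifier), function(fam) {
    a <- runs[runs$classifier == fam & runs$eval_set == "lab_test", metric]
    b <- runs[runs$classifier == fam & runs$eval_set == "realworld", metric]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    p <- if (stats::var(c(a, b)) == 0) NA_real_
         else stats::kruskal.test(list(a, b))$p.value
    data.frame(classifier = fam, median_in_domain = stats::median(a),
               median_cross_domain = stats::median(b), p_value = p,
               drop = stats::median(b) < stats::median(a))
  })
  do.call(rbind, out)
}

#' Window-length sweep
#'
#' Reruns the workflow for several epoch lengths (default 250, 500 and 750
#' samples, i.e. 1.25 s, 2.5 s and 3.75 s at 200 Hz) for the SVM family, to
#' probe how epoch duration affects in- and cross-domain performance.
#'
#' @param lab,realworld datasets as in [run_workflow()].
#' @param lengths epoch lengths in samples.
#' @param config base [experiment_config()]; `window_samples` is overridden
#'   per length and `families` restricted to `"svm"`.
#' @return named list of `fall_experiment`s (class `fall_sweep`).
#' @export
window_length_sweep <- function(lab, realworld, lengths = c(250, 500, 750),
                                config = experiment_config()) {
  if (any(lengths < 2)) xf_stop("lengths must be >= 2 samples", "invalid_argument")
  out <- lapply(lengths, function(W) {
    cfg <- config
    cfg$window_samples <- as.integer(W)
    cfg$families <- "svm"
    run_workflow(lab, realworld, cfg)
  })
  names(out) <- paste0("W", lengths)
  structure(out, class = "fall_sweep")
}

#' @export
print.fall_sweep <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]])
  }
  invisible(x)
}
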