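#' Classifier specification
#'
#' @param family `"svm"`, `"knn"` or `"rf"`.
#' @param hyperparams named list: SVM `C`, `kernel` (default linear),
#'   `kernel_scale` (gamma, non-linear kernels only); kNN `k` (Euclidean
#'   distance); RF `max_split_features` (mtry), `max_levels` (terminal-node
#'   budget, the analogue of a depth/level cap), `min_leaf` (nodesize),
#'   `ntree`.
#' @export
classifier_spec <- function(family = c("svm", "knn", "rf"), hyperparams = list()) {
  family <- match.arg(family)
  hp <- utils::modifyList(default_hyperparams(family), hyperparams)
  structure(list(family = family, hyperparams = hp), class = "classifier_spec")
}

#' Default hyperparameters per classifier family
#' @param family `"svm"`, `"knn"` or `"rf"`.
#' @export
default_hyperparams <- function(family) {
  switch(family,
         svm = list(C = 1, kernel = "linear", kernel_scale = 1),
         knn = list(k = 5),
         rf = list(max_split_features = 6, max_levels = 50, min_leaf = 1,
                   ntree = 100),
         xf_stop("unknown family", "invalid_argument"))
}

#' Hyperparameter search grid
#'
#' Default ranges follow the tuning protocol: SVM `C` in \[0.01, 10\]
#' (log-spaced), kNN `k` in 1..10, RF `max_split_features` in \[1, 17\],
#' `max_levels` in \[30, 80\] and `min_leaf` in \[1, 48\] (log-spaced
#' integers). Rows are ordered so that the first score maximum is the
#' simplest model: smaller C, larger k, smaller `max_levels` then larger
#' `min_leaf` then smaller `max_split_features`.
#'
#' @param family classifier family.
#' @param n_points grid resolution per continuous range (default 7).
#' @return data.frame of hyperparameter combinations.
#' @export
hyperparam_grid <- function(family = c("svm", "knn", "rf"), n_points = 7) {
  family <- match.arg(family)
  logspace <- function(lo, hi, n)
    pmin(pmax(exp(seq(log(lo), log(hi), length.out = n)), lo), hi)
  int_logspace <- function(lo, hi, n) unique(round(logspace(lo, hi, n)))
  switch(family,
         svm = data.frame(C = logspace(0.01, 10, n_points), kernel = "linear",
                          stringsAsFactors = FALSE),
         knn = data.frame(k = 10:1),
         rf = {
           g <- expand.grid(max_split_features = int_logspace(1, 17, n_points),
                            min_leaf = rev(int_logspace(1, 48, n_points)),
                            max_levels = int_logspace(30, 80, n_points))
           g[order(g$max_levels, -g$min_leaf, g$max_split_features), ]
         })
}

## internal: fit one classifier; X a numeric matrix (standardized), y a factor
fit_family <- function(family, hp, X, y, seed = 1) {
  switch(family,
         svm = {
           args <- list(x = X, y = y, kernel = hp$kernel, cost = hp$C,
                        scale = FALSE)
           if (hp$kernel != "linear") args$gamma <- hp$kernel_scale
           do.call(e1071::svm, args)
         },
         knn = list(X = X, y = y, k = hp$k),
         rf = {
           if (hp$min_leaf >= nrow(X)) {
             ## single-leaf degenerate limit: no split can keep every leaf at
             ## min_leaf observations, so the forest collapses to the majority
             ## class (the backend does not enforce this stopping rule itself)
             tab <- table(y)
             structure(list(majority = names(tab)[which.max(tab)],
                            levels = levels(y)),
                       class = "rf_majority_stub")
           } else with_seed(seed,
             randomForest::randomForest(
               x = X, y = y, ntree = hp$ntree,
               mtry = min(hp$max_split_features, ncol(X)),
               maxnodes = hp$max_levels,
               nodesize = hp$min_leaf))
         })
}

predict_family <- function(family, fit, X) {
  switch(family,
         svm = stats::predict(fit, X),
         knn = class::knn(fit$X, X, fit$y, k = min(fit$k, nrow(fit$X))),
         rf = if (inherits(fit, "rf_majority_stub"))
           factor(rep(fit$majority, nrow(X)), levels = fit$levels)
         else stats::predict(fit, X))
}

#' Fit a fall-detection classifier
#'
#' The central fitting function: trains one classifier family on a
#' standardized feature matrix, optionally restricted to a feature subset,
#' and freezes the training-set standardization inside the returned model so
#' that later predictions on any dataset reuse it unchanged.
#'
#' @param x a standardized [feature_matrix()] (see [standardize()]).
#' @param family `"svm"`, `"knn"` or `"rf"`.
#' @param hyperparams named list overriding [default_hyperparams()].
#' @param selected_features integer indices of the feature subset (default:
#'   all columns).
#' @param seed integer seed (random forest bootstrap).
#' @return object of class `fall_classifier` with elements `spec`, `fit`,
#'   `selected_features`, `standardization`, `provenance`.
#' @export
fall_classifier <- function(x, family = c("svm", "knn", "rf"),
                            hyperparams = list(), selected_features = NULL,
                            seed = 1) {
  family <- match.arg(family)
  if (!inherits(x, "feature_matrix"))
    xf_stop("x must be a feature_matrix", "invalid_argument")
  y <- droplevels(x$labels)
  if (nlevels(y) < 2L)
    xf_stop("training labels contain a single class", "invalid_argument")
  y <- factor(as.character(y), levels = c("ADL", "FALL"))
  if (is.null(selected_features)) selected_features <- seq_len(ncol(x$x))
  spec <- classifier_spec(family, hyperparams)
  fit <- fit_family(family, spec$hyperparams, x$x[, selected_features, drop = FALSE],
                    y, seed = seed)
  structure(list(spec = spec, fit = fit,
                 selected_features = selected_features,
                 feature_names = colnames(x$x)[selected_features],
                 standardization = x$standardization,
                 provenance = list(n_train = nrow(x$x),
                                   subjects = sort(unique(x$subject_ids)),
                                   seed = seed)),
            class = "fall_classifier")
}

#' @export
print.fall_classifier <- function(x, ...) {
  hp <- x$spec$hyperparams
  hp_str <- paste(names(hp), vapply(hp, function(v) paste(format(v), collapse = "/"),
                                    character(1)), sep = "=", collapse = ", ")
  cat(sprintf("<fall_classifier> %s (%s); %d/%d features; trained on %d segments from %d subjects\n",
              toupper(x$spec$family), hp_str, length(x$selected_features),
              if (!is.null(x$standardization)) length(x$standardization$center) else NA,
              x$provenance$n_train, length(x$provenance$subjects)))
  invisible(x)
}

#' @export
summary.fall_classifier <- function(object, ...) {
  print(object)
  cat("selected features:", paste(object$feature_names, collapse = ", "), "\n")
  invisible(object)
}

#' Predict fall/ADL labels
#'
#' @param object a [fall_classifier()].
#' @param newdata a [feature_matrix()] or plain feature matrix. Raw (non-
#'   standardized) input is transformed with the model's frozen training
#'   standardization; input already standardized (a `feature_matrix` whose
#'   `standardization` field is set) is used as-is.
#' @param ... unused.
#' @return factor of predictions with levels ADL, FALL.
#' @export
predict.fall_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) {
    X <- newdata$x
    std_done <- !is.null(newdata$standardization)
  } else {
    X <- as.matrix(newdata)
    std_done <- FALSE
  }
  if (!std_done) {
    if (is.null(object$standardization))
      xf_stop("model has no stored standardization for raw input", "invalid_argument")
    X <- sweep(sweep(X, 2, object$standardization$center), 2,
               object$standardization$scale, "/")
  }
  X <- X[, object$selected_features, drop = FALSE]
  factor(as.character(predict_family(object$spec$family, object$fit, X)),
         levels = c("ADL", "FALL"))
}

#' Subject-grouped k-fold assignment
#'
#' Assigns whole subjects to folds so no subject is split across folds.
#'
#' @param subject_ids character vector, one entry per row.
#' @param k number of folds (capped at the number of distinct subjects).
#' @param seed integer seed for the subject shuffle.
#' @return integer fold id per row.
#' @export
group_kfold <- function(subject_ids, k = 5, seed = 1) {
  subs <- sort(unique(subject_ids))
  k <- min(k, length(subs))
  perm <- with_seed(seed, sample(subs))
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(subs)), perm)
  unname(fold_of[subject_ids])
}

## internal: subject-grouped cross-validated accuracy of one configuration
cv_accuracy <- function(X, y, subject_ids, family, hp, folds = 5, seed = 1) {
  fid <- group_kfold(subject_ids, folds, seed)
  accs <- vapply(sort(unique(fid)), function(f) {
    tr <- fid != f
    if (nlevels(droplevels(y[tr])) < 2L) return(NA_real_)
    fit <- fit_family(family, hp, X[tr, , drop = FALSE], y[tr], seed = seed + f)
    mean(predict_family(family, fit, X[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

#' Sequential backward feature selection
#'
#' Starts from the full feature set and repeatedly removes the feature whose
#' removal maximizes the subject-grouped cross-validated accuracy (computed
#' with the family's default hyperparameters); stops when no removal improves
#' the score by more than `tolerance`. Ties between removals are broken by
#' removing the highest-index candidate, so the lowest-index of two equivalent
#' features survives. Never returns an empty subset.
#'
#' @param x a standardized [feature_matrix()].
#' @param family classifier family scored during selection.
#' @param folds number of grouped CV folds.
#' @param tolerance required score improvement to accept a removal (>= 0).
#' @param seed integer seed (fold assignment and forest bootstraps).
#' @param hyperparams hyperparameters used by the scorer (default:
#'   [default_hyperparams()]).
#' @return sorted integer vector of selected feature indices; attribute
#'   `score_path` records the accepted-removal score sequence.
#' @export
sequential_backward_selection <- function(x, family = c("svm", "knn", "rf"),
                                          folds = 5, tolerance = 0, seed = 1,
                                          hyperparams = list()) {
  family <- match.arg(family)
  if (tolerance < 0) xf_stop("tolerance must be >= 0", "invalid_argument")
  hp <- utils::modifyList(default_hyperparams(family), hyperparams)
  y <- factor(as.character(x$labels), levels = c("ADL", "FALL"))
  current <- seq_len(ncol(x$x))
  if (length(current) < 2L) return(current)
  score <- cv_accuracy(x$x[, current, drop = FALSE], y, x$subject_ids,
                       family, hp, folds, seed)
  path <- score
  if (is.infinite(tolerance))
    return(structure(current, score_path = path))
  repeat {
    if (length(current) == 1L) break
    cand <- vapply(seq_along(current), function(i)
      cv_accuracy(x$x[, current[-i], drop = FALSE], y, x$subject_ids,
                  family, hp, folds, seed), numeric(1))
    best <- max(cand)
    if (!(best > score + tolerance)) break
    drop_i <- max(which(cand == best))  # remove highest index on ties
    current <- current[-drop_i]
    score <- best
    path <- c(path, score)
  }
  structure(sort(current), score_path = path)
}

#' Grid-search hyperparameter tuning
#'
#' Exhaustive evaluation of a hyperparameter grid by subject-grouped k-fold
#' cross-validated accuracy. Rows are visited in the grid's simplicity order
#' and the first maximum wins, so ties resolve toward the simpler model. The
#' returned specification is then frozen for all validation sets.
#'
#' @param x a standardized [feature_matrix()] (restricted to the selected
#'   features beforehand if feature selection is used).
#' @param family classifier family.
#' @param grid data.frame as from [hyperparam_grid()].
#' @param folds number of grouped CV folds.
#' @param seed integer seed.
#' @return a [classifier_spec()] with attribute `cv_score`.
#' @export
grid_search <- function(x, family = c("svm", "knn", "rf"),
                        grid = hyperparam_grid(family), folds = 5, seed = 1) {
  family <- match.arg(family)
  if (nrow(grid) == 0L) xf_stop("empty grid", "invalid_argument")
  y <- factor(as.character(x$labels), levels = c("ADL", "FALL"))
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    hp <- utils::modifyList(default_hyperparams(family),
                            as.list(grid[i, , drop = FALSE]))
    cv_accuracy(x$x, y, x$subject_ids, family, hp, folds, seed)
  }, numeric(1))
  best <- which.max(scores)  # first maximum = simplest by grid ordering
  spec <- classifier_spec(family, as.list(grid[best, , drop = FALSE]))
  attr(spec, "cv_score") <- scores[best]
  spec
}
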