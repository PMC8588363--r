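#' Summation channel of a segment
#'
#' Combines the three axes into the single channel s(t) used as the fourth
#' feature channel. The default is the absolute summation
#' `s(t) = |ax| + |ay| + |az|`; a Euclidean-norm alternative is available via
#' `method = "euclidean"`.
#'
#' @param segment an [accel_segment()] or an n-by-3 matrix.
#' @param method `"l1"` (absolute summation, default) or `"euclidean"`.
#' @return numeric vector.
#' @export
summation_channel <- function(segment, method = c("l1", "euclidean")) {
  method <- match.arg(method)
  m <- if (inherits(segment, "accel_segment")) segment$samples else as.matrix(segment)
  if (nrow(m) == 0L) xf_stop("empty segment", "invalid_argument")
  magnitude(m, method = method)
}

#' Normalized spectral entropy of a signal
#'
#' Shannon entropy of the normalized one-sided power spectrum (DC bin
#' included), `-sum(p_i log p_i) / log(n_bins)` with `p_i = |FFT_i|^2 / sum`.
#' Ranges from 0 (all power in one bin: constant or pure DC signal) towards 1
#' (white noise). An all-zero series is defined as 0 by convention.
#'
#' @param series numeric vector, length >= 8.
#' @param rate sampling rate in Hz (kept for interface symmetry; the
#'   normalized entropy does not depend on it).
#' @export
spectral_entropy <- function(series, rate = NULL) {
  n <- length(series)
  if (n < 8L) xf_stop("series must have length >= 8", "invalid_argument")
  nb <- n %/% 2L + 1L
  P <- Mod(stats::fft(series))[1:nb]^2
  tot <- sum(P)
  if (tot == 0) return(0)
  p <- P / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(nb)
}

#' Canonical names of the 36 features
#'
#' Channel blocks x, y, z, s; within each block: mean, median, std, var, min,
#' max, q25, q75, spectral_entropy.
#' @export
feature_names <- function() {
  feats <- c("mean", "median", "std", "var", "min", "max", "q25", "q75",
             "spectral_entropy")
  as.vector(vapply(c("x", "y", "z", "s"),
                   function(ch) paste(ch, feats, sep = "_"), character(9)))
}

#' Extract the 36-dimensional feature vector of a segment
#'
#' Eight time-domain features (mean, median, sd, variance, min, max, 0.25 and
#' 0.75 quantiles, all with sample (n-1) variance and linear-interpolation
#' quantiles) plus the normalized spectral entropy, computed on each axis and
#' on the summation channel s(t).
#'
#' @param segment an [accel_segment()] or n-by-3 matrix, n >= 8.
#' @param s_method channel combination for s(t), see [summation_channel()].
#' @return named numeric vector of length 36 in [feature_names()] order.
#' @export
extract_features <- function(segment, s_method = "l1") {
  m <- if (inherits(segment, "accel_segment")) segment$samples else as.matrix(segment)
  if (nrow(m) < 8L) xf_stop("segment must have >= 8 samples", "invalid_argument")
  chans <- cbind(m, summation_channel(m, method = s_method))
  out <- apply(chans, 2, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    c(mean(v), stats::median(v), stats::sd(v), stats::var(v), min(v), max(v),
      q[1], q[2], spectral_entropy(v))
  })
  stats::setNames(as.vector(out), feature_names())
}

#' Feature matrix with labels and subject ids
#'
#' @param x numeric matrix, rows = segments, 36 columns named as in
#'   [feature_names()].
#' @param labels factor/character of `"FALL"`/`"ADL"` per row.
#' @param subject_ids subject identifier per row (for grouped splitting).
#' @param trial optional trial index per row.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, labels, subject_ids, trial = NULL) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = c("ADL", "FALL"))
  if (nrow(x) != length(labels) || nrow(x) != length(subject_ids))
    xf_stop("rows, labels and subject_ids must have equal length", "invalid_argument")
  structure(list(x = x, labels = labels, subject_ids = as.character(subject_ids),
                 trial = if (is.null(trial)) rep(NA_integer_, nrow(x)) else as.integer(trial),
                 standardization = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features (%d FALL, %d ADL), %d subjects%s\n",
              nrow(x$x), ncol(x$x), sum(x$labels == "FALL"), sum(x$labels == "ADL"),
              length(unique(x$subject_ids)),
              if (!is.null(x$standardization)) ", standardized" else ""))
  invisible(x)
}

#' Build the feature matrix of a list of segments
#'
#' @param segments list of [accel_segment()]s.
#' @param subject_ids per-segment subject ids (default: each segment's
#'   `source_trace`).
#' @param trial optional per-segment trial index.
#' @param s_method see [summation_channel()].
#' @return a [feature_matrix()].
#' @export
extract_feature_matrix <- function(segments, subject_ids = NULL, trial = NULL,
                                   s_method = "l1") {
  if (length(segments) == 0L) xf_stop("no segments", "invalid_argument")
  X <- t(vapply(segments, extract_features, numeric(36), s_method = s_method))
  labs <- vapply(segments, function(s) s$label, character(1))
  if (is.null(subject_ids))
    subject_ids <- vapply(segments, function(s) s$source_trace, character(1))
  feature_matrix(X, labs, subject_ids, trial = trial)
}

#' Standardize feature matrices with training-set statistics
#'
#' Each feature of `train` is scaled to mean 0, sd 1 using its own statistics;
#' every matrix in `others` is transformed with the TRAINING statistics (never
#' its own), as required for frozen cross-dataset evaluation. A feature that
#' is constant in training keeps sd treated as 1 (its standardized column is
#' all zeros) with a warning.
#'
#' @param train a [feature_matrix()] (non-empty).
#' @param others list of [feature_matrix()]s to transform with train stats.
#' @return list with `train`, `others`, `center`, `scale`.
#' @export
standardize <- function(train, others = list()) {
  if (!inherits(train, "feature_matrix") || nrow(train$x) == 0L)
    xf_stop("train must be a non-empty feature_matrix", "invalid_argument")
  center <- colMeans(train$x)
  scale_ <- apply(train$x, 2, stats::sd)
  if (any(scale_ == 0)) {
    warning("constant feature(s) in training set; sd treated as 1: ",
            paste(colnames(train$x)[scale_ == 0], collapse = ", "))
    scale_[scale_ == 0] <- 1
  }
  apply_std <- function(fm) {
    fm$x <- sweep(sweep(fm$x, 2, center), 2, scale_, "/")
    fm$standardization <- list(center = center, scale = scale_)
    fm
  }
  list(train = apply_std(train), others = lapply(others, apply_std),
       center = center, scale = scale_)
}
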