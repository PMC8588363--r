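#' Fixed-length labeled window of a trace
#'
#' @param samples W-by-3 numeric matrix in g.
#' @param rate sampling rate in Hz.
#' @param label `"FALL"` or `"ADL"`.
#' @param source_trace id of the parent trace.
#' @param start_index 0-based sample offset of the window in the parent trace
#'   (half-open `[start, start + W)` convention).
#' @param aligned `TRUE` when the window was selected by impact alignment.
#' @export
accel_segment <- function(samples, rate, label = c("ADL", "FALL"),
                          source_trace = "", start_index = 0L, aligned = FALSE) {
  label <- match.arg(label)
  samples <- as.matrix(samples)
  structure(list(samples = samples, rate = rate, length = nrow(samples),
                 label = label, source_trace = source_trace,
                 start_index = as.integer(start_index), aligned = aligned),
            class = "accel_segment")
}

#' @export
print.accel_segment <- function(x, ...) {
  cat(sprintf("<accel_segment> %s: %d samples @ %g Hz from %s[%d, %d)%s\n",
              x$label, x$length, x$rate, x$source_trace, x$start_index,
              x$start_index + x$length, if (x$aligned) " (impact-aligned)" else ""))
  invisible(x)
}

#' Epoch a trace into fixed-length windows
#'
#' Cuts non-overlapping (`overlap_fraction = 0`) or 50%-overlapping windows of
#' `window_samples` samples; any trailing partial window is discarded. With
#' overlap 0 the number of windows is `floor(N / W)`; with overlap 0.5 it is
#' `floor((N - W) / (W/2)) + 1` for `N >= W` and 0 otherwise.
#'
#' @param trace an [accel_trace()].
#' @param window_samples window length in samples (>= 2).
#' @param overlap_fraction 0 or 0.5.
#' @param label label assigned to each window (defaults to the trace hint,
#'   falling back to `"ADL"`).
#' @return list of [accel_segment()]s.
#' @export
epoch <- function(trace, window_samples = 500L, overlap_fraction = 0,
                  label = NULL) {
  W <- as.integer(window_samples)
  if (W < 2L) xf_stop("window_samples must be >= 2", "invalid_argument")
  if (!overlap_fraction %in% c(0, 0.5))
    xf_stop("overlap_fraction must be 0 or 0.5", "invalid_argument")
  if (is.null(label))
    label <- if (trace$label_hint == "FALL") "FALL" else "ADL"
  N <- nrow(trace$data)
  step <- if (overlap_fraction == 0) W else W %/% 2L
  if (N < W) return(list())
  starts <- seq(0L, N - W, by = step)
  lapply(starts, function(s)
    accel_segment(trace$data[(s + 1L):(s + W), , drop = FALSE], trace$rate,
                  label = label, source_trace = trace$subject_id,
                  start_index = s))
}

#' Sample entropy parameters
#'
#' @param m embedding dimension (>= 1); default 2.
#' @param r tolerance as a fraction of the window standard deviation;
#'   default 0.2.
#' @param channel `"magnitude"` (SampEn of the Euclidean magnitude) or
#'   `"per-axis"` (mean SampEn over the three axes).
#' @export
sampen_params <- function(m = 2L, r = 0.2, channel = c("magnitude", "per-axis")) {
  channel <- match.arg(channel)
  if (m < 1L) xf_stop("m must be >= 1", "invalid_argument")
  if (r <= 0) xf_stop("r must be > 0", "invalid_argument")
  structure(list(m = as.integer(m), r = r, channel = channel),
            class = "sampen_params")
}

#' Sample entropy of a one-dimensional series
#'
#' SampEn = -ln(A/B) where B counts pairs of length-`m` templates and A pairs
#' of length-`m+1` templates whose Chebyshev distance is at most
#' `r * sd(series)`; only the first `n - m` templates are used for both
#' lengths and self-matches are excluded (Richman-Moorman convention).
#' Returns 0 for a constant series and `NA` (the undefined marker, meaning
#' maximal irregularity: no length-`m+1` match at all) when A = 0.
#'
#' @param series numeric vector of length > m + 1.
#' @param params a [sampen_params()].
#' @export
sample_entropy <- function(series, params = sampen_params()) {
  m <- params$m
  n <- length(series)
  if (n <= m + 1L) xf_stop("series too short for the embedding dimension",
                           "invalid_argument")
  r <- params$r * stats::sd(series)
  if (r == 0) return(0)
  A <- 0; B <- 0
  for (lag in seq_len(n - m - 1L)) {
    d <- abs(series[1:(n - lag)] - series[(1 + lag):n])
    k <- n - m - lag
    Dm <- d[1:k]
    for (j in seq_len(m - 1L)) Dm <- pmax(Dm, d[(1 + j):(k + j)])
    Dm1 <- pmax(Dm, d[(1 + m):(k + m)])
    B <- B + sum(Dm <= r)
    A <- A + sum(Dm1 <= r)
  }
  if (A == 0) return(NA_real_)
  -log(A / B)
}

## internal: SampEn of a segment under the configured channel
segment_sampen <- function(seg, params) {
  if (params$channel == "magnitude")
    sample_entropy(magnitude(seg$samples), params)
  else
    mean(vapply(1:3, function(j) sample_entropy(seg$samples[, j], params),
                numeric(1)), na.rm = TRUE)
}

#' Locate the fall-impact window of a trace known to contain one fall
#'
#' Epochs the trace, computes SampEn per window, and among windows whose
#' SampEn reaches `threshold` returns the one with maximal SampEn as the FALL
#' segment. All other windows of a fall trial are discarded (not labeled ADL),
#' since pre-/post-fall transients are neither clean ADL nor falls. An
#' undefined SampEn (no template match) is treated as maximally irregular.
#'
#' @param trace an [accel_trace()] containing one fall.
#' @param window_samples window length in samples.
#' @param params a [sampen_params()].
#' @param threshold entropy threshold (see [calibrate_threshold()]).
#' @param overlap_fraction 0 or 0.5.
#' @return list (class `alignment_result`) with `fall_segment_index` (1-based
#'   window index), `sampen_values`, `threshold` and `segment` (the selected
#'   [accel_segment()], `aligned = TRUE`).
#' @export
locate_fall_window <- function(trace, window_samples = 500L,
                               params = sampen_params(), threshold = 0,
                               overlap_fraction = 0) {
  segs <- epoch(trace, window_samples, overlap_fraction, label = "FALL")
  if (length(segs) == 0L)
    xf_stop("trace shorter than one window", "invalid_argument")
  se <- vapply(segs, segment_sampen, numeric(1), params = params)
  cmp <- ifelse(is.na(se), Inf, se)
  if (max(cmp) < threshold)
    xf_stop(sprintf("no window reaches the SampEn threshold %.3f (max %.3f)",
                    threshold, max(cmp)), "no_event_found")
  idx <- which.max(cmp)
  seg <- segs[[idx]]
  seg$aligned <- TRUE
  structure(list(fall_segment_index = idx, sampen_values = se,
                 threshold = threshold, segment = seg),
            class = "alignment_result")
}

#' Calibrate the SampEn threshold separating impact windows from ADL
#'
#' Returns the midpoint between the largest SampEn over all windows of the
#' ADL traces and the smallest per-fall-trial maximal SampEn. Fails (class
#' `xfall_calibration_failure`) when the two ranges overlap, reporting both
#' boundary values.
#'
#' @param fall_traces,adl_traces lists of [accel_trace()]s (>= 1 each).
#' @param window_samples,params,overlap_fraction as in [locate_fall_window()].
#' @export
calibrate_threshold <- function(fall_traces, adl_traces, window_samples = 500L,
                                params = sampen_params(), overlap_fraction = 0) {
  if (length(fall_traces) < 1L || length(adl_traces) < 1L)
    xf_stop("need at least one trace of each kind", "invalid_argument")
  max_se <- function(trace) {
    segs <- epoch(trace, window_samples, overlap_fraction)
    se <- vapply(segs, segment_sampen, numeric(1), params = params)
    max(ifelse(is.na(se), Inf, se))
  }
  adl_max <- max(vapply(adl_traces, max_se, numeric(1)))
  fall_min <- min(vapply(fall_traces, max_se, numeric(1)))
  if (adl_max >= fall_min)
    stop(errorCondition(
      sprintf("no separating threshold: ADL max SampEn %.4f >= fall min %.4f",
              adl_max, fall_min),
      adl_max = adl_max, fall_min = fall_min,
      class = c("xfall_calibration_failure", "xfall_error")))
  (adl_max + fall_min) / 2
}

#' Label a real-world trace around a known impact time
#'
#' Applies the fixed convention for continuous real-world recordings: the 4 s
#' before the fall event, `[impact - 5.5, impact - 1.5)`, is labeled ADL and
#' epoched into `window_seconds` sub-windows (non-overlapping; 50% overlap is
#' used if that yields no full window), and the 2.5 s spanning 1.5 s before to
#' 1.0 s after the impact is the FALL segment. The FALL segment duration is
#' always 2.5 s regardless of `window_seconds`.
#'
#' @param trace an [accel_trace()].
#' @param impact_time impact apex in seconds (default: the trace's own).
#' @param window_seconds ADL sub-window length in seconds (default 2.5).
#' @return list of [accel_segment()]s (ADL windows first, FALL segment last).
#' @export
label_realworld <- function(trace, impact_time = trace$impact_time,
                            window_seconds = 2.5) {
  if (is.na(impact_time))
    xf_stop("impact_time is required", "invalid_argument")
  rate <- trace$rate
  if (impact_time < 5.5)
    xf_stop("need >= 5.5 s before the impact (4 s ADL + 1.5 s margin)",
            "labeling_error")
  n <- nrow(trace$data)
  fall_start <- round((impact_time - 1.5) * rate)
  fall_len <- round(2.5 * rate)
  if (fall_start + fall_len > n)
    xf_stop("trace ends before impact + 1.0 s", "labeling_error")
  adl_start <- round((impact_time - 5.5) * rate)
  adl_len <- round(4 * rate)
  W <- round(window_seconds * rate)
  adl_data <- trace$data[(adl_start + 1):(adl_start + adl_len), , drop = FALSE]
  sub <- accel_trace(adl_data, rate, subject_id = trace$subject_id,
                     activity = trace$activity, label_hint = "ADL")
  adl_segs <- epoch(sub, W, 0, label = "ADL")
  if (length(adl_segs) == 0L) adl_segs <- epoch(sub, W, 0.5, label = "ADL")
  if (length(adl_segs) == 0L)
    xf_stop("ADL context shorter than one window", "labeling_error")
  ## re-base start indices onto the parent trace
  adl_segs <- lapply(adl_segs, function(s) {
    s$start_index <- as.integer(s$start_index + adl_start)
    s$source_trace <- trace$subject_id
    s
  })
  fall_seg <- accel_segment(
    trace$data[(fall_start + 1):(fall_start + fall_len), , drop = FALSE],
    rate, label = "FALL", source_trace = trace$subject_id,
    start_index = fall_start, aligned = TRUE)
  c(adl_segs, list(fall_seg))
}
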