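#' Tri-axial accelerometer trace
#'
#' Container for one continuous tri-axial recording in units of g. Sampling is
#' uniform; time is implicit. `impact_time`, when known (simulated falls or
#' hand-annotated real-world events), is the time of the impact apex in seconds
#' from the start of the trace.
#'
#' @param data numeric matrix with three columns (`ax`, `ay`, `az`) in g.
#' @param rate sampling rate in Hz (> 0).
#' @param subject_id subject identifier string.
#' @param activity activity code (e.g. `"D01"` for an ADL, `"F03"` for a fall).
#' @param label_hint one of `"ADL"`, `"FALL"`, `"UNKNOWN"`.
#' @param impact_time impact apex in seconds, or `NA` when unknown.
#' @param domain `"lab"` or `"realworld"`.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(data, rate, subject_id = "S00", activity = "UNKNOWN",
                        label_hint = c("UNKNOWN", "ADL", "FALL"),
                        impact_time = NA_real_, domain = c("lab", "realworld")) {
  label_hint <- match.arg(label_hint)
  domain <- match.arg(domain)
  data <- as.matrix(data)
  if (ncol(data) != 3L)
    xf_stop("trace data must have exactly 3 columns (ax, ay, az)", "invalid_argument")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    xf_stop("rate must be a single positive number", "invalid_argument")
  storage.mode(data) <- "double"
  colnames(data) <- c("ax", "ay", "az")
  dur <- nrow(data) / rate
  if (!is.na(impact_time) && (impact_time < 0 || impact_time > dur))
    xf_stop("impact_time outside [0, duration]", "invalid_argument")
  structure(
    list(data = data, rate = rate, subject_id = subject_id, activity = activity,
         label_hint = label_hint, impact_time = impact_time, domain = domain),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %s/%s [%s, %s]: %d samples @ %g Hz (%.2f s)%s\n",
              x$subject_id, x$activity, x$label_hint, x$domain,
              nrow(x$data), x$rate, nrow(x$data) / x$rate,
              if (!is.na(x$impact_time)) sprintf(", impact at %.2f s", x$impact_time) else ""))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace an `accel_trace`.
#' @export
trace_duration <- function(trace) nrow(trace$data) / trace$rate

#' Magnitude channel of a trace or sample matrix
#'
#' Combines the three axes into a single magnitude-like channel. `"l1"` is the
#' absolute summation |ax| + |ay| + |az|; `"euclidean"` is the vector norm.
#'
#' @param x an `accel_trace` or an n-by-3 numeric matrix.
#' @param method `"euclidean"` (default for event localization) or `"l1"`.
#' @return numeric vector of per-sample magnitudes.
#' @export
magnitude <- function(x, method = c("euclidean", "l1")) {
  method <- match.arg(method)
  m <- if (inherits(x, "accel_trace")) x$data else as.matrix(x)
  if (method == "euclidean") sqrt(rowSums(m^2)) else rowSums(abs(m))
}

## internal: classed error helper so callers can test failure modes precisely
xf_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("xfall_", class), "xfall_error")))
}
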