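#' ADC specification
#'
#' Conversion constants between raw ADC counts and acceleration in g. The
#' default matches the published settings of the SisFall primary accelerometer
#' (+/- 16 g full scale, 13-bit resolution).
#'
#' @param range_g full-scale range in g (+/-).
#' @param resolution_bits ADC resolution, 8..16 bits.
#' @export
adc_spec <- function(range_g = 16, resolution_bits = 13) {
  if (range_g <= 0) xf_stop("range_g must be > 0", "invalid_argument")
  if (resolution_bits < 8 || resolution_bits > 16)
    xf_stop("resolution_bits must be in [8, 16]", "invalid_argument")
  structure(list(range_g = range_g, resolution_bits = as.integer(resolution_bits)),
            class = "adc_spec")
}

#' Convert raw ADC counts to acceleration in g
#'
#' Linear, sign-preserving mapping `a = (2 * range_g / 2^resolution_bits) * raw`.
#'
#' @param raw integer counts (vectorized); must satisfy
#'   `|raw| <= 2^(resolution_bits - 1)`.
#' @param spec an [adc_spec()].
#' @export
counts_to_g <- function(raw, spec = adc_spec()) {
  lim <- 2^(spec$resolution_bits - 1)
  if (any(abs(raw) > lim, na.rm = TRUE))
    xf_stop("raw count outside ADC range", "range_error")
  (2 * spec$range_g / 2^spec$resolution_bits) * raw
}

#' Convert acceleration in g to the nearest ADC count
#' @inheritParams counts_to_g
#' @param a acceleration in g.
#' @export
g_to_counts <- function(a, spec = adc_spec()) {
  step <- 2 * spec$range_g / 2^spec$resolution_bits
  raw <- round(a / step)
  lim <- 2^(spec$resolution_bits - 1)
  pmin(pmax(raw, -lim), lim)
}

#' Write a dataset as SisFall-dialect text files plus a manifest
#'
#' One file per trace named `<ACT>_<SUBJ>_R<TRIAL>.txt` holding 9 comma-
#' separated integer columns (primary accelerometer x/y/z in ADC counts,
#' then six zero columns standing in for the gyroscope and secondary
#' accelerometer), rows terminated by a semicolon. `manifest.csv` records
#' trace id, subject, activity, trial, label, impact time and rate.
#'
#' @param dataset an `accel_dataset` (see [generate_lab_cohort()]).
#' @param dir output directory (created if missing).
#' @param adc an [adc_spec()].
#' @return invisibly, the manifest with a `file` column.
#' @export
write_dataset <- function(dataset, dir, adc = adc_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$file <- paste0(man$trace_id, ".txt")
  for (i in seq_along(dataset$traces)) {
    tr <- dataset$traces[[i]]
    cnt <- apply(tr$data, 2, g_to_counts, spec = adc)
    rows <- cbind(cnt, matrix(0L, nrow(cnt), 6))
    txt <- paste0(apply(rows, 1, paste, collapse = ","), ";")
    writeLines(txt, file.path(dir, man$file[i]))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read one SisFall-dialect text file
#'
#' Parses comma-separated integer rows (a trailing semicolon per row is
#' tolerated), selects three columns via `column_map`, converts them to g, and
#' recovers subject/activity/trial metadata from the `<ACT>_<SUBJ>_R<TRIAL>`
#' file-name pattern. Activities whose code starts with `F` are hinted FALL.
#'
#' @param path file path.
#' @param adc an [adc_spec()].
#' @param column_map integer vector of length 3 selecting the accelerometer
#'   columns (default 1:3, the primary accelerometer).
#' @param rate sampling rate in Hz of the stored data (default 200).
#' @param impact_time optional known impact time in seconds.
#' @return an [accel_trace()].
#' @export
read_sisfall_dialect <- function(path, adc = adc_spec(), column_map = 1:3,
                                 rate = 200, impact_time = NA_real_) {
  if (!file.exists(path)) xf_stop(paste("no such file:", path), "format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) xf_stop("empty file", "format_error")
  lines <- sub(";\\s*$", "", lines)
  parts <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < max(column_map)))
    xf_stop(sprintf("row %d has %d columns, need >= %d",
                    which(ncols < max(column_map))[1],
                    ncols[which(ncols < max(column_map))[1]], max(column_map)),
            "format_error")
  if (length(unique(ncols)) != 1L)
    xf_stop(sprintf("ragged rows: first differing row %d",
                    which(ncols != ncols[1])[1]), "parse_error")
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    xf_stop(sprintf("malformed row at line %d", bad[1]), "parse_error")
  raw <- do.call(rbind, vals)[, column_map, drop = FALSE]
  g <- counts_to_g(raw, adc)
  base <- sub("\\.[^.]*$", "", basename(path))
  toks <- strsplit(base, "_", fixed = TRUE)[[1]]
  act <- if (length(toks) >= 1) toks[1] else "UNKNOWN"
  subj <- if (length(toks) >= 2) toks[2] else "S00"
  hint <- if (startsWith(act, "F")) "FALL" else if (startsWith(act, "D")) "ADL" else "UNKNOWN"
  accel_trace(g, rate, subject_id = subj, activity = act, label_hint = hint,
              impact_time = impact_time)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir directory containing `manifest.csv` and the trace files.
#' @param adc an [adc_spec()].
#' @param column_map column selection, as in [read_sisfall_dialect()].
#' @return an `accel_dataset`.
#' @export
read_dataset <- function(dir, adc = adc_spec(), column_map = 1:3) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  traces <- lapply(seq_len(nrow(man)), function(i) {
    tr <- read_sisfall_dialect(file.path(dir, man$file[i]), adc = adc,
                               column_map = column_map, rate = man$rate[i],
                               impact_time = man$impact_time_s[i])
    tr$subject_id <- man$subject[i]
    tr$activity <- man$activity[i]
    tr$label_hint <- man$label[i]
    tr
  })
  structure(list(traces = traces, manifest = man), class = "accel_dataset")
}

#' Write / read a trace as generic CSV (`ax,ay,az` in g)
#' @param trace an [accel_trace()].
#' @param path CSV file path.
#' @export
write_accel_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace$data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_accel_csv
#' @param rate sampling rate of the stored samples.
#' @param ... passed to [accel_trace()].
#' @export
read_accel_csv <- function(path, rate, ...) {
  d <- utils::read.csv(path)
  if (!all(c("ax", "ay", "az") %in% names(d)))
    xf_stop("CSV must have columns ax, ay, az", "format_error")
  accel_trace(as.matrix(d[, c("ax", "ay", "az")]), rate, ...)
}

#' Resample a trace to a new rate with FIR anti-aliasing
#'
#' Classic polyphase (upfirdn) rational-rate resampling applied per axis:
#' zero-stuff by p, filter with a Kaiser-windowed linear-phase FIR low-pass at
#' the tighter of the two Nyquist limits, keep every q-th sample, and
#' compensate the filter delay. The signal mean is removed before filtering
#' and restored afterwards, so constant signals are preserved exactly.
#' Output length is `round(n * target_rate / rate)`.
#'
#' @param trace an [accel_trace()].
#' @param target_rate output rate in Hz.
#' @return a resampled [accel_trace()] (impact time, in seconds, unchanged).
#' @export
resample_trace <- function(trace, target_rate) {
  if (target_rate <= 0) xf_stop("target_rate must be > 0", "invalid_argument")
  if (target_rate == trace$rate) return(trace)
  frac <- rational_ratio(target_rate, trace$rate)
  n <- nrow(trace$data)
  n_out <- round(n * target_rate / trace$rate)
  out <- vapply(1:3, function(j)
    resample_fir(trace$data[, j], frac[1], frac[2], n_out), numeric(n_out))
  accel_trace(out, target_rate, subject_id = trace$subject_id,
              activity = trace$activity, label_hint = trace$label_hint,
              impact_time = trace$impact_time, domain = trace$domain)
}

## internal: polyphase FIR resampling of one channel (upfirdn with delay
## compensation); 10 filter lobes per polyphase branch, Kaiser beta = 5.
resample_fir <- function(x, p, q, n_out) {
  n <- length(x)
  L <- max(p, q)
  ntaps <- 2L * 10L * L + 1L
  h <- signal::fir1(ntaps - 1, 1 / L, window = signal::kaiser(ntaps, 5)) * p
  mu <- mean(x)
  up <- numeric(n * p)
  up[seq(1L, by = p, length.out = n)] <- x - mu
  y_full <- stats::convolve(up, rev(h), type = "open")
  delay <- (ntaps - 1L) / 2L
  idx <- delay + 1L + seq(0L, by = q, length.out = n_out)
  y <- y_full[pmin(idx, length(y_full))] + mu
  y
}

## internal: small-integer ratio p/q ~ a/b
rational_ratio <- function(a, b) {
  ## scale to integers (rates may be non-integer), then reduce by gcd
  k <- 1
  while (abs(a * k - round(a * k)) > 1e-9 || abs(b * k - round(b * k)) > 1e-9) {
    k <- k * 10
    if (k > 1e6) xf_stop("cannot express rate ratio as a small fraction",
                         "invalid_argument")
  }
  ai <- round(a * k); bi <- round(b * k)
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  d <- g(ai, bi)
  c(ai / d, bi / d)
}
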