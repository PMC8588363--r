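test_that("epoching counts and reconstruction follow the window arithmetic", {
  tr <- simulate_adl("walking", 15, 200, seed = 1)  # N = 3000
  expect_length(epoch(tr, 500, 0), 6L)
  expect_length(epoch(tr, 500, 0.5), 11L)
  short <- accel_trace(matrix(rnorm(499 * 3), 499, 3), 200)
  expect_length(epoch(short, 500, 0), 0L)
  expect_error(epoch(tr, 500, 0.25), class = "xfall_invalid_argument")
  expect_error(epoch(tr, 1), class = "xfall_invalid_argument")

  # concatenating non-overlapping segments reproduces the truncated trace
  tr2 <- accel_trace(matrix(rnorm(1730 * 3), 1730, 3), 200)
  segs <- epoch(tr2, 400, 0)
  expect_length(segs, 4L)
  rec <- do.call(rbind, lapply(segs, function(s) s$samples))
  expect_identical(rec, tr2$data[1:1600, ])
  expect_equal(vapply(segs, function(s) s$start_index, integer(1)),
               c(0L, 400L, 800L, 1200L))
})

test_that("sample entropy matches the brute-force template-counting oracle", {
  # constant series
  expect_identical(sample_entropy(rep(3, 50)), 0)
  # short periodic series, exact agreement with the oracle
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  expect_identical(sample_entropy(x, sampen_params(2, 0.2)),
                   sampen_oracle(x, 2, 0.2))
  # white noise n = 500
  set.seed(42)
  w <- rnorm(500)
  expect_equal(sample_entropy(w), sampen_oracle(w), tolerance = 1e-12)
  # 50 seeded series of mixed character, multiple embedding dimensions
  for (s in 1:50) {
    set.seed(s)
    n <- sample(30:300, 1)
    kind <- s %% 3
    x <- if (kind == 0) rnorm(n)
         else if (kind == 1) sin(2 * pi * 3 * (1:n) / n) + rnorm(n, 0, 0.2)
         else cumsum(rnorm(n))
    m <- 1 + s %% 3
    got <- sample_entropy(x, sampen_params(m, 0.2))
    want <- sampen_oracle(x, m, 0.2)
    expect_equal(got, want, tolerance = 1e-12, label = paste("seed", s))
  }
  expect_error(sample_entropy(c(1, 2, 3), sampen_params(2, 0.2)),
               class = "xfall_invalid_argument")
})

test_that("sample entropy returns the undefined marker when no m+1 match exists", {
  x <- c(0, 0, 1000, -1000, 500, -500)
  expect_true(is.na(sample_entropy(x, sampen_params(1, 0.2))))
  expect_true(is.na(sampen_oracle(x, 1, 0.2)))
})

test_that("impact localization picks the impact window and rejects pure ADL", {
  res <- make_fall_trace(seed = 11)
  al <- locate_fall_window(res$trace, 500, threshold = 0)
  # impact at ~6 s -> third of six non-overlapping 2.5 s windows
  expect_identical(al$fall_segment_index, 3L)
  w0 <- al$segment$start_index / res$trace$rate
  expect_true(res$impact_time >= w0 && res$impact_time < w0 + 2.5)
  expect_true(al$segment$aligned)
  expect_length(al$sampen_values, 6L)

  # calibrated threshold: ADL traces yield no event
  fall_traces <- lapply(1:5, function(s) make_fall_trace(seed = s)$trace)
  adl_traces <- lapply(1:5, function(s) simulate_adl("walking", seed = 50 + s))
  th <- calibrate_threshold(fall_traces, adl_traces)
  expect_error(locate_fall_window(adl_traces[[1]], 500, threshold = th),
               class = "xfall_no_event_found")
  # threshold 0 still selects the max-SampEn window
  al0 <- locate_fall_window(fall_traces[[1]], 500, threshold = 0)
  expect_identical(al0$fall_segment_index,
                   which.max(ifelse(is.na(al0$sampen_values), Inf,
                                    al0$sampen_values)))
})

test_that("threshold calibration returns the midpoint or fails on overlap", {
  fall <- make_fall_trace(seed = 2)$trace
  adl <- simulate_adl("walking", seed = 3)
  params <- sampen_params()
  max_se <- function(tr) {
    max(vapply(epoch(tr, 500), function(s)
      sample_entropy(magnitude(s$samples), params), numeric(1)), na.rm = TRUE)
  }
  th <- calibrate_threshold(list(fall), list(adl), 500, params)
  expect_equal(th, (max_se(adl) + max_se(fall)) / 2, tolerance = 1e-12)

  # swapping roles forces an overlap -> calibration failure with boundaries
  err <- tryCatch(calibrate_threshold(list(adl), list(fall), 500, params),
                  error = identity)
  expect_s3_class(err, "xfall_calibration_failure")
  expect_true(err$adl_max >= err$fall_min)
  expect_error(calibrate_threshold(list(), list(adl)),
               class = "xfall_invalid_argument")
})

test_that("impact window dominates SampEn on seeded fall traces", {
  params <- sampen_params()
  for (s in 1:30) {
    res <- make_fall_trace(seed = 1000 + s)
    segs <- epoch(res$trace, 500)
    se <- vapply(segs, function(sg)
      sample_entropy(magnitude(sg$samples), params), numeric(1))
    se <- ifelse(is.na(se), Inf, se)
    iw <- floor(res$impact_time * res$trace$rate / 500) + 1
    expect_identical(which.max(se), as.integer(iw), label = paste("seed", s))
  }
})

test_that("real-world labeling follows the fixed 4 s / 2.5 s convention", {
  set.seed(5)
  tr <- accel_trace(matrix(rnorm(1500 * 3, 0, 0.1), 1500, 3) + 1, 100,
                    impact_time = 10)
  segs <- label_realworld(tr, impact_time = 10)
  fall <- segs[[length(segs)]]
  expect_identical(fall$label, "FALL")
  expect_identical(fall$start_index, 850L)           # (10 - 1.5) * 100
  expect_identical(fall$length, 250L)                # 2.5 s at 100 Hz
  expect_identical(fall$samples, tr$data[851:1100, ])
  adl <- segs[-length(segs)]
  expect_true(all(vapply(adl, function(s) s$label, character(1)) == "ADL"))
  expect_true(all(vapply(adl, function(s) s$start_index, integer(1)) >= 450L))

  # FALL duration is 2.5 s regardless of the ADL sub-window length
  for (ws in c(1.25, 2.5, 3.75)) {
    segs2 <- label_realworld(tr, impact_time = 10, window_seconds = ws)
    expect_identical(segs2[[length(segs2)]]$length, 250L)
  }
  expect_error(label_realworld(tr, impact_time = 3), class = "xfall_labeling_error")
  expect_error(label_realworld(tr, impact_time = 14.8), class = "xfall_labeling_error")
})
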