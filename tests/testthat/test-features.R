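test_that("summation channel is the per-sample absolute sum", {
  expect_equal(summation_channel(matrix(c(1, 0, 0), 1)), 1)
  expect_equal(summation_channel(matrix(c(-1, 2, -2), 1)), 5)
  expect_equal(summation_channel(matrix(c(-1, 2, -2), 1), method = "euclidean"), 3)
  gravity <- matrix(rep(c(0, 0, 1), each = 10), 10)
  expect_equal(summation_channel(gravity), rep(1, 10))
  expect_error(summation_channel(matrix(numeric(0), 0, 3)),
               class = "xfall_invalid_argument")
})

test_that("spectral entropy matches the direct-definition oracle", {
  expect_identical(spectral_entropy(rep(2, 64)), 0)
  expect_identical(spectral_entropy(numeric(16)), 0)
  set.seed(1)
  w <- rnorm(512)
  expect_equal(spectral_entropy(w), spectral_entropy_oracle(w), tolerance = 1e-9)
  expect_gt(spectral_entropy(w), 0.8)   # white noise is near-maximal
  tone <- sin(2 * pi * 8 * (0:511) / 512)  # bin-centred frequency
  expect_lt(spectral_entropy(tone), 0.1)
  expect_equal(spectral_entropy(tone), spectral_entropy_oracle(tone),
               tolerance = 1e-9)
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(128) + sin(2 * pi * s * (0:127) / 128)
    expect_equal(spectral_entropy(x), spectral_entropy_oracle(x),
                 tolerance = 1e-9, label = paste("seed", s))
  }
  expect_error(spectral_entropy(1:4), class = "xfall_invalid_argument")
})

test_that("feature extraction yields the 36 canonical features", {
  seg <- accel_segment(matrix(rnorm(1500), 500, 3), 200)
  fv <- extract_features(seg)
  expect_length(fv, 36L)
  expect_identical(names(fv), feature_names())

  # constant segment: location features = c, spread and entropy zero
  cseg <- accel_segment(matrix(2, 16, 3), 200)
  fc <- extract_features(cseg)
  for (ch in c("x", "y", "z")) {
    for (f in c("mean", "median", "min", "max", "q25", "q75"))
      expect_equal(unname(fc[paste(ch, f, sep = "_")]), 2)
    expect_equal(unname(fc[paste0(ch, "_std")]), 0)
    expect_equal(unname(fc[paste0(ch, "_spectral_entropy")]), 0)
  }
  expect_equal(unname(fc["s_mean"]), 6)

  # linear-interpolation quantiles: column 1,1,2,2,3,3,4,4
  qseg <- accel_segment(cbind(rep(1:4, each = 2), rep(0, 8), rep(0, 8)), 200)
  fq <- extract_features(qseg)
  expect_equal(unname(fq["x_q25"]), 1.75)
  expect_equal(unname(fq["x_q75"]), 3.25)
  expect_error(extract_features(accel_segment(matrix(1, 4, 3), 200)),
               class = "xfall_invalid_argument")
})

test_that("feature invariants: order statistics, variance, scale equivariance", {
  set.seed(7)
  for (s in 1:10) {
    seg <- matrix(rnorm(300, sd = runif(1, 0.5, 3)), 100, 3)
    fv <- extract_features(accel_segment(seg, 200))
    for (ch in c("x", "y", "z", "s")) {
      g <- function(f) unname(fv[paste(ch, f, sep = "_")])
      expect_true(g("min") <= g("q25") && g("q25") <= g("median") &&
                    g("median") <= g("q75") && g("q75") <= g("max"))
      expect_equal(g("var"), g("std")^2, tolerance = 1e-12)
      expect_true(g("spectral_entropy") >= 0 && g("spectral_entropy") <= 1)
    }
    # scale equivariance
    c0 <- 2.5
    fv2 <- extract_features(accel_segment(c0 * seg, 200))
    for (ch in c("x", "y", "z", "s")) {
      for (f in c("mean", "median", "std", "min", "max", "q25", "q75"))
        expect_equal(unname(fv2[paste(ch, f, sep = "_")]),
                     c0 * unname(fv[paste(ch, f, sep = "_")]), tolerance = 1e-9)
      expect_equal(unname(fv2[paste0(ch, "_var")]),
                   c0^2 * unname(fv[paste0(ch, "_var")]), tolerance = 1e-9)
      expect_equal(unname(fv2[paste0(ch, "_spectral_entropy")]),
                   unname(fv[paste0(ch, "_spectral_entropy")]), tolerance = 1e-9)
    }
  }
})

test_that("standardization uses training statistics everywhere", {
  set.seed(3)
  X <- matrix(rnorm(50 * 36, mean = 2, sd = 4), 50, 36,
              dimnames = list(NULL, feature_names()))
  train <- feature_matrix(X, rep(c("ADL", "FALL"), 25), rep("S1", 50))
  test_same <- train
  shifted <- feature_matrix(X + 10, rep(c("ADL", "FALL"), 25), rep("S2", 50))
  std <- standardize(train, list(test_same, shifted))
  expect_true(all(abs(colMeans(std$train$x)) < 1e-9))
  expect_true(all(abs(apply(std$train$x, 2, sd) - 1) < 1e-9))
  # identical test matrix -> identical standardized values
  expect_equal(std$others[[1]]$x, std$train$x)
  # shifted matrix keeps its shift (transformed with TRAIN stats, not its own)
  expect_true(all(colMeans(std$others[[2]]$x) > 1))

  # degenerate feature: zeros plus a warning, never NaN
  Xc <- X; Xc[, 5] <- 7
  trc <- feature_matrix(Xc, rep(c("ADL", "FALL"), 25), rep("S1", 50))
  expect_warning(stdc <- standardize(trc), "constant feature")
  expect_true(all(stdc$train$x[, 5] == 0))
  expect_false(anyNA(stdc$train$x))
  expect_error(standardize(feature_matrix(X[0, , drop = FALSE], character(0),
                                          character(0))),
               class = "xfall_invalid_argument")
})

test_that("feature matrices serialize losslessly through CSV", {
  co <- generate_lab_cohort(
    cohort_spec(n_subjects = 1, n_trials_per_activity = 1, trial_duration = 5,
                seed = 6),
    activity_catalog(fall_types = character(0),
                     adl_types = sisfall_adl_types()[1:2]))
  segs <- unlist(lapply(co$traces, epoch, window_samples = 500), recursive = FALSE)
  fm <- extract_feature_matrix(segs)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cbind(as.data.frame(fm$x), label = as.character(fm$labels),
                         subject_id = fm$subject_ids), f, row.names = FALSE)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(as.matrix(back[, feature_names()]), fm$x,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$label, as.character(fm$labels))
})
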