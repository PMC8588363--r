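# Independent oracles used to cross-check the implementation.

# Brute-force sample entropy: explicit template embedding and pairwise
# Chebyshev distances via stats::dist. Richman-Moorman convention (first
# n - m templates for both lengths, self-matches excluded).
sampen_oracle <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * stats::sd(x)
  if (r == 0) return(0)
  Nt <- n - m
  embed_templates <- function(len) {
    out <- vapply(seq_len(Nt), function(i) x[i:(i + len - 1)], numeric(len))
    if (is.null(dim(out))) matrix(out, ncol = 1) else t(out)
  }
  B <- sum(stats::dist(embed_templates(m), method = "maximum") <= r)
  A <- sum(stats::dist(embed_templates(m + 1), method = "maximum") <= r)
  if (A == 0) return(NA_real_)
  -log(A / B)
}

# Direct-definition spectral entropy via an explicit DFT matrix (no fft()).
spectral_entropy_oracle <- function(x) {
  n <- length(x)
  k <- 0:(n %/% 2)
  P <- vapply(k, function(kk)
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)))^2, numeric(1))
  tot <- sum(P)
  if (tot == 0) return(0)
  p <- P / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(k))
}

# Tiny ready-made fall/ADL trace factories for segmentation tests.
make_fall_trace <- function(seed, impact_peak = 6, ...) {
  simulate_fall(phase_params = fall_phase_params(impact_peak = impact_peak),
                seed = seed, ...)
}

# Balanced, linearly separable toy feature matrix (one subject per row so
# grouped CV degenerates to row-wise folds).
toy_separable_fm <- function(n = 40, p = 4, gap = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("ADL", "FALL"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + ifelse(y == "FALL", gap, 0)
  colnames(X) <- paste0("f", seq_len(p))
  fm <- feature_matrix(X, y, sprintf("S%02d", seq_len(n)))
  standardize(fm)$train
}
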