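## Internal utilities: seeded RNG scoping and rotation helpers.

## Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

## Draw n reproducible sub-seeds (31-bit) from the current RNG stream.
draw_seeds <- function(n) sample.int(.Machine$integer.max, n)

## Rotation matrix for a given axis (unit 3-vector) and angle in radians
## (Rodrigues' formula).
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Random rotation by `angle_deg` (degrees) about a uniformly random axis,
## drawn from the current RNG stream.
random_rotation <- function(angle_deg) {
  ax <- stats::rnorm(3)
  rotation_matrix(ax, angle_deg * pi / 180)
}

## Low-pass-filtered Gaussian noise rescaled to the requested sd. The smoothing
## (2nd-order Butterworth, zero phase) emulates band-limited sensor/motion
## noise; the cutoff is deliberately low so that quiet signal stretches remain
## regular on the SampEn template scale.
smooth_noise <- function(n, sd, rate, cutoff = 2.5) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  pad <- 200L
  w <- stats::rnorm(n + 2L * pad)
  bf <- signal::butter(2, min(cutoff / (rate / 2), 0.99))
  f <- signal::filtfilt(bf, w)[(pad + 1L):(n + pad)]
  s <- stats::sd(f)
  if (s == 0) return(numeric(n))
  f * sd / s
}
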