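#' Fall phase parameters
#'
#' Parameters of the invented four-phase fall model used by the simulator:
#' an ADL-like pre-fall phase, a free-fall dip, an impact phase (sharp spike
#' followed by broadband post-impact oscillation), and a low-variance rest
#' phase (lying still). All durations in seconds, amplitudes in g.
#'
#' @param prefall_duration seconds of ADL-like context before the fall.
#' @param freefall_duration seconds of free fall (magnitude drops below 0.5 g).
#' @param impact_peak apex acceleration in g; must exceed 2 g so the impact
#'   dominates ADL dynamics (default 6 g).
#' @param impact_duration total impact phase length: a short spike envelope
#'   (up to 0.35 s) plus post-impact oscillation filling the remainder.
#' @param rest_duration minimum seconds of rest required after the impact
#'   phase; the rest phase actually extends to the end of the trial.
#' @param noise_sd sd in g of the band-limited noise added in quiet phases.
#' @return object of class `fall_phase_params`.
#' @export
fall_phase_params <- function(prefall_duration = 5.5, freefall_duration = 0.4,
                              impact_peak = 6, impact_duration = 1.55,
                              rest_duration = 1, noise_sd = 0.005) {
  if (prefall_duration <= 0 || freefall_duration <= 0 || impact_duration <= 0 ||
      rest_duration <= 0)
    xf_stop("all phase durations must be > 0", "invalid_argument")
  if (impact_peak <= 2)
    xf_stop("impact_peak must exceed 2 g to dominate ADL dynamics", "invalid_argument")
  structure(list(prefall_duration = prefall_duration,
                 freefall_duration = freefall_duration,
                 impact_peak = impact_peak, impact_duration = impact_duration,
                 rest_duration = rest_duration, noise_sd = noise_sd),
            class = "fall_phase_params")
}

#' Domain shift between the lab-style and real-world-style generators
#'
#' Emulates differences in sensor placement/orientation, gain, noise floor,
#' bias and sampling rate between a waist-worn lab sensor and a lower-back
#' real-world sensor.
#'
#' @param rotation_deg mean per-event orientation perturbation in degrees.
#' @param gain multiplicative amplitude factor (> 0).
#' @param noise_sd_delta additional white noise sd in g.
#' @param baseline_offset additive per-axis bias in g.
#' @param target_rate output sampling rate in Hz (default 100).
#' @return object of class `domain_shift`.
#' @export
domain_shift <- function(rotation_deg = 25, gain = 1.1, noise_sd_delta = 0.01,
                         baseline_offset = 0.03, target_rate = 100) {
  if (gain <= 0) xf_stop("gain must be > 0", "invalid_argument")
  if (target_rate <= 0) xf_stop("target_rate must be > 0", "invalid_argument")
  structure(list(rotation_deg = rotation_deg, gain = gain,
                 noise_sd_delta = noise_sd_delta,
                 baseline_offset = baseline_offset, target_rate = target_rate),
            class = "domain_shift")
}

#' Identity domain shift (no perturbation, rate kept at 200 Hz)
#' @export
identity_shift <- function() domain_shift(rotation_deg = 0, gain = 1,
                                          noise_sd_delta = 0, baseline_offset = 0,
                                          target_rate = 200)

#' A strong domain shift used to probe generalization failure
#'
#' Large re-orientation plus a 1.5x gain, extra noise and bias: deliberately
#' harsher than the default shift so that distance- and threshold-based
#' classifiers trained on the lab domain degrade measurably.
#' @export
strong_shift <- function() domain_shift(rotation_deg = 60, gain = 1.5,
                                        noise_sd_delta = 0.03,
                                        baseline_offset = 0.1, target_rate = 100)

#' Cohort specification for the lab-style generator
#'
#' Defaults mirror the SisFall recording protocol: 23 subjects, 5 trials per
#' activity, 15 s trials sampled at 200 Hz.
#'
#' @param n_subjects,n_trials_per_activity,trial_duration,sample_rate,seed
#'   see description; `seed` drives all randomness of the cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 23, n_trials_per_activity = 5,
                        trial_duration = 15, sample_rate = 200, seed = 1) {
  if (n_subjects < 1 || n_trials_per_activity < 1)
    xf_stop("counts must be >= 1", "invalid_argument")
  if (trial_duration <= 0 || sample_rate <= 0)
    xf_stop("duration and rate must be > 0", "invalid_argument")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_activity = as.integer(n_trials_per_activity),
                 trial_duration = trial_duration, sample_rate = sample_rate,
                 seed = seed),
            class = "cohort_spec")
}

## internal: magnitude profile of an ADL stretch starting at time t0 (for
## phase continuity), around a baseline of 1 g.
adl_magnitude <- function(n, rate, amp, cadence, noise_sd, phase, t0 = 0) {
  t <- t0 + (0:(n - 1)) / rate
  1 + amp * sin(2 * pi * cadence * t + phase) + smooth_noise(n, noise_sd, rate)
}

## internal: embed a magnitude profile into three axes. `u` is the (unit)
## gravity direction; `lateral` an optional orthogonal oscillation.
embed_axes <- function(m, u, lateral = NULL, v = NULL, axis_noise = 0, rate = 200) {
  n <- length(m)
  out <- outer(m, u)
  if (!is.null(lateral)) out <- out + outer(lateral, v)
  if (axis_noise > 0)
    for (j in 1:3) out[, j] <- out[, j] + smooth_noise(n, axis_noise, rate)
  out
}

## internal: unit vector orthogonal to u
orthogonal_unit <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v / sqrt(sum(v^2))
}

#' Simulate one activity-of-daily-living trace
#'
#' The magnitude fluctuates around 1 g (gravity) with an archetype-specific
#' oscillation (e.g. gait cadence 1.5-2.5 Hz for walking) plus band-limited
#' noise; no sample exceeds 2.5 g. With `noise_sd = 0`, quiet standing yields
#' a magnitude of exactly 1 g.
#'
#' @param activity archetype description (see [sisfall_adl_types()]) or code.
#' @param duration trace length in seconds.
#' @param rate sampling rate in Hz.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param noise_sd band-limited noise sd in g.
#' @param orientation 3x3 rotation applied to the default gravity direction
#'   (0, 0, 1); models sensor placement.
#' @param gain multiplicative sensor gain.
#' @param subject_id,domain trace metadata.
#' @return an [accel_trace()] with `label_hint = "ADL"`.
#' @export
simulate_adl <- function(activity = "walking", duration = 15, rate = 200,
                         seed = NULL, noise_sd = 0.005, orientation = diag(3),
                         gain = 1, subject_id = "S00", domain = "lab") {
  if (duration <= 0 || rate <= 0)
    xf_stop("duration and rate must be > 0", "invalid_argument")
  n <- round(duration * rate)
  if (n < 1) xf_stop("duration * rate must be >= 1", "invalid_argument")
  with_seed(seed, {
    p <- adl_archetype_params(activity)
    amp <- stats::runif(1, p$amp[1], p$amp[2])
    cadence <- stats::runif(1, p$cadence[1], p$cadence[2])
    phase <- stats::runif(1, 0, 2 * pi)
    m <- adl_magnitude(n, rate, amp, cadence, noise_sd, phase)
    u <- as.vector(orientation %*% c(0, 0, 1))
    lat <- if (amp > 0) 0.25 * amp * sin(pi * cadence * ((0:(n - 1)) / rate) + phase / 2)
           else NULL
    dat <- gain * embed_axes(m, u, lateral = lat, v = orthogonal_unit(u),
                             axis_noise = 0.3 * noise_sd, rate = rate)
    accel_trace(dat, rate, subject_id = subject_id, activity = activity,
                label_hint = "ADL", domain = domain)
  })
}

#' Simulate one trial containing a single fall
#'
#' Produces a trace following the four-phase fall model: ADL-like context,
#' a free-fall dip (magnitude < 0.5 g), a sharp impact spike reaching
#' `impact_peak` with broadband post-impact oscillation, then low-variance
#' rest. The body re-orients at impact (gravity direction rotates ~90 deg),
#' as when ending up lying on the ground.
#'
#' @param fall_type label stored as the trace activity.
#' @param phase_params a [fall_phase_params()] object.
#' @param context_adl ADL archetype of the pre-fall phase.
#' @param duration,rate,seed,orientation,gain,subject_id,domain as in
#'   [simulate_adl()].
#' @return list with elements `trace` (an [accel_trace()], `label_hint =
#'   "FALL"`, `impact_time` set) and `impact_time` (seconds, the spike apex).
#' @export
simulate_fall <- function(fall_type = "F01", phase_params = fall_phase_params(),
                          context_adl = "walking", duration = 15, rate = 200,
                          seed = NULL, orientation = diag(3), gain = 1,
                          subject_id = "S00", domain = "lab") {
  pp <- phase_params
  envelope_dur <- min(0.35, pp$impact_duration)
  used <- pp$prefall_duration + pp$freefall_duration + pp$impact_duration +
    pp$rest_duration
  if (used > duration)
    xf_stop("fall phases exceed the trial duration", "invalid_argument")
  n <- round(duration * rate)
  t <- (0:(n - 1)) / rate
  with_seed(seed, {
    ## pre-fall context
    p <- adl_archetype_params(context_adl)
    amp <- stats::runif(1, max(p$amp[1], 0.15), max(p$amp[2], 0.2))
    cadence <- stats::runif(1, p$cadence[1], p$cadence[2])
    phase <- stats::runif(1, 0, 2 * pi)
    m <- adl_magnitude(n, rate, amp, cadence, pp$noise_sd, phase)

    ff0 <- pp$prefall_duration
    ff1 <- ff0 + pp$freefall_duration
    idx <- which(t >= ff0 & t < ff1)
    ## cosine ramp into near-weightlessness at 0.08 g
    m[idx] <- 0.08 + (1 - 0.08) * 0.5 * (1 + cos(pi * pmin((t[idx] - ff0) / 0.1, 1))) +
      smooth_noise(length(idx), 0.3 * pp$noise_sd, rate)

    attack <- envelope_dur * (0.1 / 0.35)
    peak_t <- ff1 + attack
    imp1 <- ff1 + envelope_dur
    idx <- which(t >= ff1 & t < imp1)
    ti <- t[idx]
    env <- ifelse(ti <= peak_t,
                  0.08 + (pp$impact_peak - 0.08) * ((ti - ff0 - pp$freefall_duration) / attack)^2,
                  1 + (pp$impact_peak - 1) * exp(-(ti - peak_t) / 0.06))
    m[idx] <- env
    apex <- which.min(abs(t - peak_t))
    m[apex] <- pp$impact_peak
    impact_time <- t[apex]

    ring1 <- ff1 + pp$impact_duration
    idx <- which(t >= imp1 & t < ring1)
    m[idx] <- 1 + stats::rnorm(length(idx), 0, 0.25)

    idx <- which(t >= ring1)
    m[idx] <- 1 + 0.06 * sin(2 * pi * 0.35 * t[idx]) +
      smooth_noise(length(idx), 0.3 * pp$noise_sd, rate)

    ## axes: gravity direction rotates at impact (body ends up lying down)
    u <- as.vector(orientation %*% c(0, 0, 1))
    u2 <- as.vector(rotation_matrix(orthogonal_unit(u),
                                    stats::runif(1, 70, 110) * pi / 180) %*% u)
    pre <- t < peak_t
    dat <- matrix(0, n, 3)
    dat[pre, ] <- embed_axes(m[pre], u, rate = rate)
    dat[!pre, ] <- embed_axes(m[!pre], u2, rate = rate)
    for (j in 1:3) dat[, j] <- dat[, j] + smooth_noise(n, 0.3 * pp$noise_sd, rate)
    dat <- gain * dat

    trace <- accel_trace(dat, rate, subject_id = subject_id, activity = fall_type,
                         label_hint = "FALL", impact_time = impact_time,
                         domain = domain)
    list(trace = trace, impact_time = impact_time)
  })
}

#' Generate a lab-style cohort
#'
#' One trace per (subject, activity, trial): every subject performs every ADL
#' and fall archetype in the catalog `n_trials_per_activity` times. Subjects
#' carry individual sensor orientations (rotations up to ~12 degrees), gains
#' (+/- 15%) and cadence tendencies so that subject-wise splitting matters.
#' Fall trials store the ground-truth impact time.
#'
#' @param spec a [cohort_spec()].
#' @param catalog an [activity_catalog()].
#' @return object of class `accel_dataset`: list with `traces` (list of
#'   [accel_trace()]) and `manifest` (data.frame with trace_id, subject,
#'   activity, trial, label, impact_time_s, rate).
#' @export
generate_lab_cohort <- function(spec = cohort_spec(), catalog = activity_catalog()) {
  acts <- c(names(catalog$adl_types), names(catalog$fall_types))
  labels <- c(rep("ADL", length(catalog$adl_types)),
              rep("FALL", length(catalog$fall_types)))
  descr <- c(catalog$adl_types, catalog$fall_types)
  n_tr <- spec$n_subjects * length(acts) * spec$n_trials_per_activity
  with_seed(spec$seed, {
    subj_rot <- lapply(seq_len(spec$n_subjects), function(i)
      random_rotation(stats::runif(1, 0, 12)))
    subj_gain <- stats::runif(spec$n_subjects, 0.85, 1.15)
    seeds <- draw_seeds(n_tr)

    traces <- vector("list", n_tr)
    man <- vector("list", n_tr)
    k <- 0L
    for (si in seq_len(spec$n_subjects)) {
      sid <- sprintf("SA%02d", si)
      for (ai in seq_along(acts)) {
        for (tr in seq_len(spec$n_trials_per_activity)) {
          k <- k + 1L
          if (labels[ai] == "ADL") {
            tc <- simulate_adl(descr[ai], spec$trial_duration, spec$sample_rate,
                               seed = seeds[k], orientation = subj_rot[[si]],
                               gain = subj_gain[si], subject_id = sid)
            it <- NA_real_
          } else {
            pp <- fall_phase_params(impact_peak = 6 * fall_peak_scale(ai - length(catalog$adl_types)))
            res <- simulate_fall(acts[ai], pp, context_adl = fall_context(descr[ai]),
                                 duration = spec$trial_duration,
                                 rate = spec$sample_rate, seed = seeds[k],
                                 orientation = subj_rot[[si]],
                                 gain = subj_gain[si], subject_id = sid)
            tc <- res$trace
            it <- res$impact_time
          }
          tc$activity <- acts[ai]
          traces[[k]] <- tc
          man[[k]] <- data.frame(trace_id = sprintf("%s_%s_R%02d", acts[ai], sid, tr),
                                 subject = sid, activity = acts[ai], trial = tr,
                                 label = labels[ai], impact_time_s = it,
                                 rate = spec$sample_rate)
        }
      }
    }
    structure(list(traces = traces, manifest = do.call(rbind, man)),
              class = "accel_dataset")
  })
}

## internal: deterministic per-archetype presets (the protocol does not specify
## kinematic differences among fall types; types differ by peak scale/context)
fall_peak_scale <- function(idx) 0.9 + 0.05 * ((idx - 1) %% 7)
fall_context <- function(description) {
  key <- tolower(description)
  if (grepl("jog", key)) "jogging"
  else if (grepl("sitting", key) || grepl("sit down", key)) "sitting down"
  else if (grepl("get up", key)) "standing up"
  else "walking"
}

#' Generate a real-world-style event set
#'
#' Continuous traces containing ADL context followed by one accidental fall
#' with known impact time, produced by the same four-phase model as the lab
#' generator and then passed through a [domain_shift()]: per-event rotation,
#' gain, white noise, baseline offset, and resampling to `shift$target_rate`.
#' Each event has at least 4 s of ADL before the fall so the fixed real-world
#' labeling convention applies.
#'
#' @param n_events number of fall events (default 15).
#' @param shift a [domain_shift()].
#' @param seed integer seed.
#' @param duration trace duration in seconds (pre-resampling, at 200 Hz).
#' @return object of class `accel_dataset` whose manifest carries the
#'   ground-truth `impact_time_s` per event.
#' @export
generate_realworld_set <- function(n_events = 15, shift = domain_shift(),
                                   seed = 1, duration = 15) {
  if (n_events < 1) xf_stop("n_events must be >= 1", "invalid_argument")
  with_seed(seed, {
    seeds <- draw_seeds(n_events)
    prefalls <- stats::runif(n_events, 5.5, 7.0)
    gains <- stats::runif(n_events, 0.85, 1.15)
    angles <- stats::rnorm(n_events, shift$rotation_deg, shift$rotation_deg / 5)
    rots <- lapply(angles, random_rotation)
    traces <- vector("list", n_events)
    man <- vector("list", n_events)
    for (i in seq_len(n_events)) {
      pp <- fall_phase_params(prefall_duration = prefalls[i],
                              impact_peak = 6 * stats::runif(1, 0.9, 1.2))
      res <- simulate_fall(sprintf("RW%02d", i), pp, duration = duration,
                           rate = 200, seed = seeds[i], gain = gains[i],
                           subject_id = sprintf("RW%02d", i), domain = "realworld")
      dat <- res$trace$data %*% t(rots[[i]])
      dat <- shift$gain * dat
      if (shift$noise_sd_delta > 0)
        dat <- dat + matrix(stats::rnorm(length(dat), 0, shift$noise_sd_delta),
                            ncol = 3)
      dat <- dat + shift$baseline_offset
      tc <- accel_trace(dat, 200, subject_id = res$trace$subject_id,
                        activity = res$trace$activity, label_hint = "FALL",
                        impact_time = res$impact_time, domain = "realworld")
      if (shift$target_rate != 200) tc <- resample_trace(tc, shift$target_rate)
      traces[[i]] <- tc
      man[[i]] <- data.frame(trace_id = tc$subject_id, subject = tc$subject_id,
                             activity = tc$activity, trial = 1L, label = "FALL",
                             impact_time_s = tc$impact_time,
                             rate = shift$target_rate)
    }
    structure(list(traces = traces, manifest = do.call(rbind, man)),
              class = "accel_dataset")
  })
}

#' @export
print.accel_dataset <- function(x, ...) {
  cat(sprintf("<accel_dataset> %d traces (%d FALL, %d ADL), %d subjects\n",
              nrow(x$manifest), sum(x$manifest$label == "FALL"),
              sum(x$manifest$label == "ADL"),
              length(unique(x$manifest$subject))))
  invisible(x)
}
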