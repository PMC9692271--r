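# Synthetic RR / ECG cohort generation.
#
# The study data (63 subjects, four stress states, 70 s per state) are private,
# so the pipeline ships an integral pulse frequency modulation (IPFM)
# generator: heartbeats are emitted each time the integral of an instantaneous
# rate r(t) crosses an integer. Band-limited sinusoidal modulation at the LF
# (0.10 Hz) and HF (0.25 Hz) band centers gives direct, independent control
# over the spectral features the classifier consumes.

#' Per-state generator parameters
#'
#' @param mean_rr Mean RR interval in seconds; must lie in (0.3, 2.0).
#' @param lf_amp Relative modulation amplitude of the 0.10 Hz (low-frequency)
#'   component, dimensionless, >= 0.
#' @param hf_amp Relative modulation amplitude of the 0.25 Hz (high-frequency)
#'   component, dimensionless, >= 0.
#' @param noise_sd Standard deviation of the broadband Gaussian rate
#'   modulation, dimensionless, >= 0.
#' @param sdnn_target Optional informational field: the approximate SDNN (s)
#'   the template aims to induce. Not enforced by the generator; RR
#'   variability follows from the modulation amplitudes.
#' @return A `state_params` list.
#' @export
state_params <- function(mean_rr, lf_amp = 0, hf_amp = 0, noise_sd = 0,
                         sdnn_target = NULL) {
  stop_if(!is_scalar_num(mean_rr) || mean_rr <= 0.3 || mean_rr >= 2.0,
          "mean_rr must lie in (0.3, 2.0) seconds")
  stop_if(lf_amp < 0 || hf_amp < 0 || noise_sd < 0,
          "modulation amplitudes must be non-negative")
  stop_if(lf_amp + hf_amp + 3 * noise_sd >= 1,
          "lf_amp + hf_amp + 3*noise_sd must be < 1 to keep the rate positive")
  structure(list(mean_rr = mean_rr, lf_amp = lf_amp, hf_amp = hf_amp,
                 noise_sd = noise_sd, sdnn_target = sdnn_target),
            class = "state_params")
}

#' Default state templates for the four stress conditions
#'
#' Mean RR decreases (heart rate rises) and the LF:HF amplitude balance tilts
#' toward LF as stress increases, following the qualitative ordering
#' resting < VR scene adaptation < recovery < VR task. The numeric values are
#' package choices of physiologically plausible magnitudes, not measured ones.
#'
#' @return Named list of [state_params], names `"resting"`, `"vr_adaptation"`,
#'   `"vr_task"`, `"recovery"` (i.e. class labels 1, 4, 2, 3).
#' @export
default_state_params <- function() {
  list(
    resting       = state_params(0.85, lf_amp = 0.03, hf_amp = 0.09, noise_sd = 0.02),
    vr_task       = state_params(0.65, lf_amp = 0.10, hf_amp = 0.04, noise_sd = 0.02),
    recovery      = state_params(0.78, lf_amp = 0.07, hf_amp = 0.06, noise_sd = 0.02),
    vr_adaptation = state_params(0.82, lf_amp = 0.05, hf_amp = 0.08, noise_sd = 0.02)
  )
}

#' Map between state names and class labels
#'
#' Class labels: 1 = resting, 2 = VR task, 3 = recovery, 4 = VR scene
#' adaptation.
#' @return Named integer vector.
#' @export
stress_labels <- function() {
  c(resting = 1L, vr_task = 2L, recovery = 3L, vr_adaptation = 4L)
}

# LF / HF modulation carrier frequencies (band centers), Hz.
LF_CARRIER <- 0.10
HF_CARRIER <- 0.25

#' Generate an RR series with the IPFM model
#'
#' Integrates the instantaneous rate
#' `r(t) = (1 + m(t)) / mean_rr` with
#' `m(t) = lf_amp sin(2 pi 0.10 t + phi1) + hf_amp sin(2 pi 0.25 t + phi2) + e(t)`,
#' where `e(t)` is Gaussian noise of standard deviation `noise_sd` held
#' piecewise-constant on the integration grid, and emits a beat each time the
#' integral crosses an integer. A beat is placed at t = 0 (integrator reset).
#'
#' @param params A [state_params] object.
#' @param duration Record duration in seconds; must exceed `2 * mean_rr`.
#' @param seed Integer seed; the output is reproducible given the seed.
#' @param dt Integration grid step in seconds.
#' @param source_id Optional identifier attached to the result.
#' @return An [rr_series]. All intervals lie in (0.3, 2.0) s for valid
#'   parameters.
#' @examples
#' rr <- generate_rr(state_params(0.8), duration = 8, seed = 1)
#' rr$intervals  # ten intervals of 0.8 s
#' @export
generate_rr <- function(params, duration, seed, dt = 0.01, source_id = NULL) {
  stopifnot(inherits(params, "state_params"))
  stop_if(!is_scalar_num(duration) || duration <= 0, "duration must be positive")
  stop_if(duration <= 2 * params$mean_rr,
          "duration must exceed twice the mean RR interval")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))

  t_grid <- seq(0, duration, by = dt)
  phi <- stats::runif(2, 0, 2 * pi)
  m <- params$lf_amp * sin(2 * pi * LF_CARRIER * t_grid + phi[1]) +
    params$hf_amp * sin(2 * pi * HF_CARRIER * t_grid + phi[2])
  if (params$noise_sd > 0) {
    m <- m + stats::rnorm(length(t_grid), 0, params$noise_sd)
  }
  rate <- (1 + m) / params$mean_rr
  # cumulative integral of the rate (trapezoid on the grid)
  cum <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * diff(t_grid)))

  n_beats <- floor(cum[length(cum)] + 1e-9)
  if (n_beats < 1L) stop("duration too short: no beat emitted", call. = FALSE)
  # invert the monotone integral at integer crossings by linear interpolation
  beat_times <- stats::approx(cum, t_grid, xout = seq_len(n_beats),
                              ties = "ordered", rule = 2)$y
  beat_times <- c(0, beat_times)
  rr_series(beat_times, source_id = source_id)
}

# Save/restore the global RNG state so generator calls are pure.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cohort configuration
#'
#' @param n_subjects Number of subjects (>= 1); the emulated study has 63.
#' @param duration_per_state Seconds of RR data per subject and state
#'   (default 70).
#' @param state_params Named list of four [state_params] templates as from
#'   [default_state_params()].
#' @param subject_jitter Relative spread of the per-subject lognormal
#'   perturbation applied to `mean_rr` and (jointly) to the LF/HF amplitudes;
#'   0 disables inter-individual variation.
#' @param seed Integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 63L, duration_per_state = 70,
                          state_params = default_state_params(),
                          subject_jitter = 0.05, seed = 20221110L) {
  stop_if(!is_count(n_subjects), "n_subjects must be a positive integer")
  stop_if(!is_scalar_num(duration_per_state) || duration_per_state <= 0,
          "duration_per_state must be positive")
  stop_if(!setequal(names(state_params), names(stress_labels())),
          "state_params must have entries resting, vr_task, recovery, vr_adaptation")
  stop_if(subject_jitter < 0, "subject_jitter must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 duration_per_state = duration_per_state,
                 state_params = state_params,
                 subject_jitter = subject_jitter,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' One RR record per subject and stress state. Each subject draws a fixed
#' triple of lognormal factors (for `mean_rr`, `lf_amp` and `hf_amp`) applied
#' identically across their four states, modeling the inter-individual
#' differences in heart rate and autonomic balance that cross-subject
#' evaluation must overcome.
#'
#' @param config A [cohort_config].
#' @return List of records, each a list with `subject_id` (integer), `state`
#'   (name), `label` (1-4 per [stress_labels()]) and `rr` ([rr_series]).
#'   Length `n_subjects * 4`; bit-reproducible given `config$seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- stress_labels()
  out <- vector("list", config$n_subjects * 4L)
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    old <- .Random.seed_save()
    set.seed(derive_seed(config$seed, s, 0L))
    jit <- exp(stats::rnorm(3, 0, config$subject_jitter))
    .Random.seed_restore(old)
    for (state in names(labels)) {
      tpl <- config$state_params[[state]]
      mrr <- min(max(tpl$mean_rr * jit[1], 0.35), 1.9)
      lf <- tpl$lf_amp * jit[2]
      hf <- tpl$hf_amp * jit[3]
      # keep the positivity invariant after jitter
      tot <- lf + hf + 3 * tpl$noise_sd
      if (tot >= 0.98) {
        shrink <- 0.97 / tot
        lf <- lf * shrink
        hf <- hf * shrink
      }
      p <- state_params(mrr, lf_amp = lf, hf_amp = hf,
                        noise_sd = tpl$noise_sd)
      k <- k + 1L
      out[[k]] <- list(
        subject_id = s,
        state = state,
        label = unname(labels[[state]]),
        rr = generate_rr(p, config$duration_per_state,
                         seed = derive_seed(config$seed, s, labels[[state]]),
                         source_id = sprintf("S%03d_%s", s, state))
      )
    }
  }
  out
}

#' Synthesize an ECG waveform from an RR series
#'
#' Places a Gaussian-bump QRS template (unit amplitude) at each beat time and
#' adds white Gaussian noise. The true beat times are retained in the result's
#' `true_beats` attribute so detector performance can be scored against ground
#' truth.
#'
#' @param rr An [rr_series] (or `NULL` for a noise-only record).
#' @param fs Sampling rate, Hz (>= 100; the emulated device records at 250).
#' @param duration Record length in seconds; defaults to the last beat time
#'   plus one mean interval.
#' @param qrs_width Width of the R-wave bump in seconds (Gaussian sigma is
#'   `qrs_width / 4`). The 0.05 s default matches the sharp R wave whose
#'   energy the 10-35 Hz detection passband is designed to keep.
#' @param noise_sd Additive noise standard deviation in the template's
#'   amplitude units.
#' @param pad Baseline seconds prepended and appended to the record, so no
#'   QRS template is bisected by a record edge; beat times (and the retained
#'   ground truth) shift by `pad`.
#' @param seed Integer seed for the noise.
#' @return An [ecg_record] with attribute `true_beats`.
#' @export
synthesize_ecg <- function(rr, fs = 250, duration = NULL, qrs_width = 0.05,
                           noise_sd = 0, pad = 0, seed = 1L) {
  stop_if(fs < 100, "fs must be at least 100 Hz")
  beats <- if (is.null(rr)) numeric(0) else rr$beat_times
  if (is.null(duration)) {
    duration <- if (length(beats)) max(beats) + mean(diff(beats)) else 1
  }
  stop_if(length(beats) && (min(beats) < 0 || max(beats) > duration),
          "beat times outside the record span")
  beats <- beats + pad
  duration <- duration + 2 * pad
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  sigma <- qrs_width / 4
  for (b in beats) {
    lo <- max(1L, floor((b - 4 * sigma) * fs) + 1L)
    hi <- min(n, ceiling((b + 4 * sigma) * fs) + 1L)
    idx <- lo:hi
    x[idx] <- x[idx] + exp(-((t[idx] - b)^2) / (2 * sigma^2))
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed %% 2147483647))
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  rec <- ecg_record(x, fs = fs, lead_labels = "lead1")
  attr(rec, "true_beats") <- beats
  rec
}

#' Write a cohort to disk
#'
#' RR series as one-interval-per-line text files plus a manifest CSV with
#' columns `subject_id`, `state`, `label`, `path`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(dir), "cannot create output directory: ", dir)
  rows <- lapply(cohort, function(rec) {
    fname <- sprintf("rr_S%03d_%s.txt", rec$subject_id, rec$state)
    write_rr(rec$rr, file.path(dir, fname))
    data.frame(subject_id = rec$subject_id, state = rec$state,
               label = rec$label, path = fname)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort manifest back into memory
#'
#' @param manifest_path Path to a manifest CSV written by [write_cohort()].
#' @return A cohort list as from [generate_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    list(subject_id = row$subject_id, state = row$state, label = row$label,
         rr = read_rr(file.path(base, row$path),
                      source_id = sprintf("S%03d_%s", row$subject_id, row$state)))
  })
}
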