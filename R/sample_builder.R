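# Turn each subject-state RR record into an N x 7 time-series sample and
# standardize each (timestep, feature) cell with min-max statistics learned on
# the training samples only.

#' Windowing configuration
#'
#' Window i (i = 1..N) covers `[(i-1) d, (i-1) d + L)` seconds, so a record
#' must span at least `L + (N-1) d` seconds (68 s at the defaults, which a
#' 70-s state record satisfies).
#'
#' @param L Window length, seconds (default 30).
#' @param d Sliding step, seconds (default 2).
#' @param N Number of windows (time steps) per sample (default 20).
#' @return A `window_config` list.
#' @export
window_config <- function(L = 30, d = 2, N = 20L) {
  stop_if(!is_scalar_num(L) || L <= 0, "L must be positive")
  stop_if(!is_scalar_num(d) || d <= 0, "d must be positive")
  stop_if(!is_count(N), "N must be a positive integer")
  structure(list(L = L, d = d, N = as.integer(N)), class = "window_config")
}

#' Required record duration for a window configuration
#' @param config A [window_config].
#' @return Seconds.
#' @export
required_duration <- function(config) {
  config$L + (config$N - 1L) * config$d
}

#' Build one N x 7 sample from an RR record
#'
#' Row i is the seven-feature HRV vector of window i. Windows are anchored at
#' the record's first beat time. Beats after `L + (N-1) d` never influence the
#' result; extra windows that would fit are not used.
#'
#' @param rr An [rr_series].
#' @param config A [window_config].
#' @param label Stress class label in 1..4 (1 = resting, 2 = VR task,
#'   3 = recovery, 4 = VR scene adaptation), or `NA` for unlabeled data.
#' @param subject_id Optional subject identifier.
#' @param min_intervals Minimum intervals a window must contain.
#' @return A `sample_matrix`: list with `values` (N x 7 matrix), `label`,
#'   `subject_id`.
#' @export
build_sample <- function(rr, config = window_config(), label = NA_integer_,
                         subject_id = NULL, min_intervals = 8L) {
  stopifnot(inherits(rr, "rr_series"), inherits(config, "window_config"))
  stop_if(!is.na(label) && !(label %in% 1:4), "label must be in 1..4")
  t0 <- rr$beat_times[1L]
  span <- max(rr$times) - t0
  need <- required_duration(config)
  stop_if(span + 1e-9 < need,
          sprintf("record spans %.1f s but %.1f s are required (L + (N-1) d)",
                  span, need))
  vals <- matrix(NA_real_, nrow = config$N, ncol = 7L,
                 dimnames = list(NULL, hrv_feature_names()))
  for (i in seq_len(config$N)) {
    w <- rr_window(rr, t0 + (i - 1L) * config$d, config$L)
    stop_if(length(w$intervals) < min_intervals,
            sprintf("window %d has only %d intervals (need >= %d): low-quality record",
                    i, length(w$intervals), min_intervals))
    vals[i, ] <- feature_vector(w$times, w$intervals)
  }
  structure(list(values = vals, label = label, subject_id = subject_id),
            class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("<sample_matrix> %d x %d, label %s, subject %s\n",
              nrow(x$values), ncol(x$values), x$label,
              x$subject_id %||% "?"))
  invisible(x)
}

#' Build samples for a whole cohort
#'
#' @param cohort Cohort list as from [generate_cohort()] / [read_cohort()].
#' @param config A [window_config].
#' @param on_short How to treat records too short (or too sparse) for the
#'   configuration: `"error"` or `"skip"` (skips are counted in attribute
#'   `n_skipped`).
#' @return List of `sample_matrix` objects.
#' @export
build_cohort_samples <- function(cohort, config = window_config(),
                                 on_short = c("error", "skip")) {
  on_short <- match.arg(on_short)
  out <- list()
  skipped <- 0L
  for (rec in cohort) {
    s <- tryCatch(
      build_sample(rec$rr, config, label = rec$label,
                   subject_id = rec$subject_id),
      error = function(e) {
        if (on_short == "error") stop(e)
        NULL
      }
    )
    if (is.null(s)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- s
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Fit per-cell min-max standardization statistics
#'
#' For every timestep i and feature j, the minimum and maximum of cell (i, j)
#' across the M training samples. Validation and test data must be
#' standardized with these training statistics, never their own.
#'
#' @param train_samples List of `sample_matrix` objects (>= 2).
#' @return A `standardization_stats` object: `min` and `max` (N x 7 matrices)
#'   and `fitted_on` (M).
#' @export
fit_standardizer <- function(train_samples) {
  stop_if(length(train_samples) < 2L, "need at least 2 training samples")
  arr <- vapply(train_samples, function(s) s$values,
                train_samples[[1L]]$values)
  structure(
    list(min = apply(arr, c(1L, 2L), min),
         max = apply(arr, c(1L, 2L), max),
         fitted_on = length(train_samples)),
    class = "standardization_stats"
  )
}

#' Standardize a sample with training min-max statistics
#'
#' Elementwise `(f - min) / (max - min)` per cell. Cells where the training
#' max equals the min map to 0. Out-of-range values on validation/test data
#' are preserved (no clipping): the linear map keeps cross-subject shift
#' information.
#'
#' @param sample A `sample_matrix` (or a list of them).
#' @param stats A `standardization_stats` from [fit_standardizer()].
#' @return The standardized sample(s), same shape.
#' @export
standardize <- function(sample, stats) {
  stopifnot(inherits(stats, "standardization_stats"))
  if (!inherits(sample, "sample_matrix") && is.list(sample)) {
    return(lapply(sample, standardize, stats = stats))
  }
  stopifnot(inherits(sample, "sample_matrix"))
  stop_if(!all(dim(sample$values) == dim(stats$min)),
          "sample shape does not match standardization statistics")
  rng <- stats$max - stats$min
  z <- (sample$values - stats$min) / ifelse(rng > 0, rng, 1)
  z[rng == 0] <- 0
  sample$values <- z
  sample
}

#' Stack samples into an array plus label/subject vectors
#'
#' @param samples List of `sample_matrix` objects.
#' @return List with `x` (M x N x 7 array), `y` (integer labels), `subjects`.
#' @export
stack_samples <- function(samples) {
  stop_if(!length(samples), "no samples to stack")
  n <- nrow(samples[[1L]]$values)
  x <- array(NA_real_, dim = c(length(samples), n, 7L))
  for (i in seq_along(samples)) x[i, , ] <- samples[[i]]$values
  list(x = x,
       y = vapply(samples, function(s) as.integer(s$label), integer(1)),
       subjects = vapply(samples, function(s) as.integer(s$subject_id), integer(1)))
}

#' Write / read standardization statistics as JSON
#' @param stats A `standardization_stats`.
#' @param path File path.
#' @export
write_standardizer <- function(stats, path) {
  jsonlite::write_json(
    list(min = stats$min, max = stats$max, fitted_on = stats$fitted_on),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = x$min, max = x$max, fitted_on = x$fitted_on),
            class = "standardization_stats")
}
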