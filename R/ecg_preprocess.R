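# ECG preprocessing: bandpass filtering, R-wave detection, RR extraction.

#' Zero-phase Butterworth bandpass filter
#'
#' Fourth-order Butterworth bandpass with 10-35 Hz cutoffs, applied
#' forward-backward (`signal::filtfilt`) per lead so that R-peak times are not
#' lag-shifted. The passband keeps the QRS complex while removing baseline
#' wander and movement artifacts below 10 Hz and high-frequency noise above
#' 35 Hz.
#'
#' @param record An [ecg_record] with `fs > 70` (Nyquist above the upper
#'   cutoff).
#' @param low,high Cutoff frequencies in Hz.
#' @param order Filter order (applied once per direction).
#' @return A filtered [ecg_record], same length and sampling rate.
#' @export
bandpass_filter <- function(record, low = 10, high = 35, order = 4L) {
  stopifnot(inherits(record, "ecg_record"))
  stop_if(record$fs <= 2 * high,
          sprintf("sampling rate %g Hz too low: need fs > %g Hz (twice the upper cutoff)",
                  record$fs, 2 * high))
  bf <- signal::butter(order, c(low, high) / (record$fs / 2), type = "pass")
  # odd-symmetric reflection padding suppresses the start/end transients of
  # the forward-backward pass (cf. scipy.signal.filtfilt's default padding)
  n_pad <- min(nrow(record$samples) - 1L, as.integer(round(record$fs)))
  filtered <- apply(record$samples, 2L, function(x) {
    head_pad <- 2 * x[1L] - x[(n_pad + 1L):2L]
    n <- length(x)
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - n_pad)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[(n_pad + 1L):(n_pad + n)]
  })
  out <- ecg_record(filtered, fs = record$fs, lead_labels = record$lead_labels)
  attr(out, "true_beats") <- attr(record, "true_beats")
  out
}

#' Detect R waves
#'
#' Pan-Tompkins-style detection chain on the (10-35 Hz bandpassed) primary
#' lead: squaring, 150 ms moving-window integration, adaptive thresholding
#' with running signal/noise peak estimates and a 250 ms refractory period.
#' Accepted candidates are refined to the local maximum of the filtered
#' waveform within +/- 100 ms, so symmetric QRS complexes are localized to the
#' sample.
#'
#' @param record An [ecg_record], at least 2 s long.
#' @param lead Index of the lead to analyze (default 1).
#' @param prefiltered Set `TRUE` if `record` has already been bandpass
#'   filtered; otherwise [bandpass_filter()] is applied internally.
#' @param refractory Minimum beat spacing in seconds.
#' @return Numeric vector of strictly increasing beat times in seconds
#'   (empty, with a warning, if nothing crosses threshold).
#' @export
detect_r_peaks <- function(record, lead = 1L, prefiltered = FALSE,
                           refractory = 0.25) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  stop_if(nrow(record$samples) < 2 * fs, "record shorter than 2 s")
  if (!prefiltered) record <- bandpass_filter(record)
  x <- record$samples[, lead]

  sq <- x^2
  win <- max(1L, round(0.150 * fs))
  # centered moving-window integration keeps energy peaks aligned with the QRS
  mwi <- stats::filter(sq, rep(1 / win, win), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  n <- length(mwi)
  is_max <- c(FALSE, mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                mwi[2:(n - 1)] >= mwi[3:n], FALSE)
  cand <- which(is_max)
  if (!length(cand) || max(mwi) <= 0) {
    warning("no R peaks found")
    return(numeric(0))
  }

  # adaptive threshold: running estimates of signal and noise peak levels
  spki <- max(mwi[seq_len(min(n, round(2 * fs)))]) * 0.75
  npki <- 0
  thr <- npki + 0.25 * (spki - npki)
  refr <- round(refractory * fs)
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (mwi[i] >= thr) {
      if (i - last >= refr) {
        peaks <- c(peaks, i)
        last <- i
        spki <- 0.125 * mwi[i] + 0.875 * spki
      } else if (mwi[i] > mwi[last]) {
        # stronger peak inside the refractory window replaces the previous one
        peaks[length(peaks)] <- i
        last <- i
        spki <- 0.125 * mwi[i] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (!length(peaks)) {
    warning("no R peaks found")
    return(numeric(0))
  }

  # refine each event to the filtered-signal maximum near the energy peak
  half <- round(0.100 * fs)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement
  keep <- c(TRUE, diff(refined) >= refr)
  while (!all(keep)) {
    refined <- refined[keep]
    keep <- c(TRUE, diff(refined) >= refr)
  }
  (refined - 1L) / fs
}

#' RR intervals from beat times
#'
#' Successive differences of the detected beat times, with a physiologic
#' artifact rule: intervals outside `[0.3, 2.0]` s are removed (their later
#' beat is marked invalid). If more than 10% of the intervals are dropped the
#' result is flagged low quality via attribute `low_quality` (the record is
#' not auto-excluded).
#'
#' @param beat_times Strictly increasing beat times in seconds (>= 2 beats).
#' @param min_rr,max_rr Physiologic bounds in seconds.
#' @param source_id Optional identifier.
#' @return An [rr_series] containing only valid intervals; attributes
#'   `n_dropped` and `low_quality` record the artifact filtering outcome.
#' @export
to_rr <- function(beat_times, min_rr = 0.3, max_rr = 2.0, source_id = NULL) {
  stop_if(length(beat_times) < 2L, "need at least 2 beats")
  stop_if(any(diff(beat_times) <= 0), "beat times must be strictly increasing")
  iv <- diff(beat_times)
  tm <- beat_times[-1L]
  ok <- iv >= min_rr & iv <= max_rr
  n_drop <- sum(!ok)
  stop_if(sum(ok) < 1L, "no valid RR intervals after artifact filtering")
  # rebuild beat times so that kept intervals abut: cumulative sum of kept
  # intervals, time-stamped by their true later-beat times
  rr <- structure(
    list(
      beat_times = beat_times,
      intervals = iv[ok],
      times = tm[ok],
      source_id = source_id
    ),
    class = "rr_series"
  )
  attr(rr, "n_dropped") <- n_drop
  attr(rr, "low_quality") <- n_drop > 0.1 * length(iv)
  rr
}
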