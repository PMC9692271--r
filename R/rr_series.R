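#' RR-interval series
#'
#' Container for a sequence of heartbeats: beat times in seconds and the
#' inter-beat (RR) intervals derived from them. Each retained interval carries
#' the time stamp of its *later* beat, which is what spectral estimation on the
#' irregularly sampled tachogram uses.
#'
#' @param beat_times Numeric vector of beat times in seconds, strictly
#'   increasing.
#' @param source_id Optional subject/state identifier string.
#' @return An object of class `rr_series` with fields `beat_times`,
#'   `intervals` (seconds), `times` (time stamp of each interval, seconds) and
#'   `source_id`.
#' @examples
#' rr <- rr_series(c(0, 0.8, 1.6, 2.4))
#' rr$intervals
#' @export
rr_series <- function(beat_times, source_id = NULL) {
  stop_if(length(beat_times) < 2L, "an RR series needs at least 2 beats")
  stop_if(any(!is.finite(beat_times)), "beat times must be finite")
  stop_if(any(diff(beat_times) <= 0), "beat times must be strictly increasing")
  structure(
    list(
      beat_times = as.numeric(beat_times),
      intervals = diff(as.numeric(beat_times)),
      times = as.numeric(beat_times[-1L]),
      source_id = source_id
    ),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d intervals over %.1f s (mean RR %.3f s)%s\n",
    length(x$intervals), diff(range(x$beat_times)), mean(x$intervals),
    if (is.null(x$source_id)) "" else paste0(" [", x$source_id, "]")
  ))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Slice an RR series to a time window
#'
#' Returns the intervals whose later beat falls in `[start, start + width)`;
#' an interval straddling a window boundary is assigned to the window
#' containing its later beat.
#'
#' @param rr An [rr_series].
#' @param start Window start time, seconds.
#' @param width Window width, seconds.
#' @return List with `intervals` and `times` (both possibly empty).
#' @export
rr_window <- function(rr, start, width) {
  stopifnot(inherits(rr, "rr_series"))
  keep <- rr$times >= start & rr$times < start + width
  list(intervals = rr$intervals[keep], times = rr$times[keep])
}

#' Write / read RR interval text files
#'
#' One interval per line, in seconds. The plain-text format is the lingua
#' franca for tachograms and round-trips through any HRV toolkit.
#'
#' @param rr An [rr_series].
#' @param path File path.
#' @return `write_rr` returns `path` invisibly; `read_rr` returns an
#'   [rr_series] whose beat times start at the first interval (a beat is
#'   assumed at t = 0).
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(sprintf("%.17g", rr$intervals), path)
  invisible(path)
}

#' @rdname write_rr
#' @export
read_rr <- function(path, source_id = NULL) {
  x <- as.numeric(readLines(path))
  stop_if(length(x) < 1L || any(!is.finite(x)) || any(x <= 0),
          "invalid RR file: ", path)
  rr_series(cumsum(c(0, x)), source_id = source_id)
}

#' ECG record
#'
#' A sampled ECG waveform: one column per lead, constant sampling rate.
#'
#' @param samples Numeric vector (single lead) or matrix with one column per
#'   lead, amplitudes in mV or arbitrary units.
#' @param fs Sampling rate in Hz.
#' @param lead_labels Optional character vector of lead names.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, lead_labels = NULL) {
  stop_if(!is_scalar_num(fs) || fs <= 0, "fs must be a positive number")
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  stop_if(!is.numeric(samples), "samples must be numeric")
  if (!is.null(lead_labels)) {
    stop_if(length(lead_labels) != ncol(samples),
            "lead_labels length must match the number of leads")
    colnames(samples) <- lead_labels
  }
  structure(
    list(samples = samples, fs = fs, n_leads = ncol(samples),
         lead_labels = colnames(samples)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d leads, %d samples @ %g Hz (%.1f s)\n",
              x$n_leads, nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Write / read ECG records as CSV
#'
#' Column `time` (seconds) followed by one column per lead.
#'
#' @param record An [ecg_record].
#' @param path File path.
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  n <- nrow(record$samples)
  df <- data.frame(time = (seq_len(n) - 1L) / record$fs)
  leads <- record$samples
  colnames(leads) <- record$lead_labels %||% paste0("lead", seq_len(record$n_leads))
  utils::write.csv(cbind(df, as.data.frame(leads)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stop_if(!"time" %in% names(df), "ECG CSV needs a 'time' column: ", path)
  dt <- diff(df$time)
  stop_if(any(dt <= 0), "time column must be strictly increasing")
  fs <- 1 / stats::median(dt)
  leads <- as.matrix(df[setdiff(names(df), "time")])
  ecg_record(leads, fs = fs, lead_labels = colnames(leads))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
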