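# The seven HRV features computed on an RR-interval window:
# mRR, SDNN (time domain), HFn, LFn, LF/HF (frequency domain, Lomb-Scargle on
# the irregularly sampled tachogram), ApEn (entropy), SD1/SD2 (Poincare).

#' Feature names in fixed slot order
#' @return Character vector of length 7.
#' @export
hrv_feature_names <- function() {
  c("mRR", "SDNN", "HFn", "LFn", "LF_HF", "ApEn", "SD1_SD2")
}

#' Mean RR interval
#' @param intervals Numeric vector of RR intervals in seconds (>= 1).
#' @return Arithmetic mean, seconds.
#' @export
mean_rr <- function(intervals) {
  stop_if(length(intervals) < 1L, "mean_rr needs at least one interval")
  mean(intervals)
}

#' SDNN: standard deviation of RR intervals
#'
#' Population convention (divide by n), so a two-interval segment has a
#' deterministic closed form and SDNN is scale-equivariant.
#'
#' @param intervals Numeric vector of RR intervals in seconds (>= 2).
#' @return Standard deviation, seconds.
#' @export
sdnn <- function(intervals) {
  stop_if(length(intervals) < 2L, "sdnn needs at least two intervals")
  pop_sd(intervals)
}

# Frequency grid for band power integration (Hz).
LF_BAND <- c(0.04, 0.15)
HF_BAND <- c(0.15, 0.40)
FREQ_STEP <- 0.002

# Classic Lomb-Scargle periodogram of an unevenly sampled, mean-subtracted
# series, evaluated at frequencies `freqs` (Hz). Unnormalized convention
# (power in units of y^2), vectorized over frequencies.
#' @noRd
lomb_psd <- function(times, values, freqs) {
  y <- values - mean(values)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    ct <- cos(w * (times - tau))
    st <- sin(w * (times - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
}

#' LF and HF band powers of the tachogram
#'
#' Lomb-Scargle periodogram of the mean-subtracted RR series on the fixed grid
#' 0.04-0.40 Hz (step 0.002 Hz), integrated by the trapezoid rule over the LF
#' band 0.04-0.15 Hz and the HF band 0.15-0.40 Hz (the 0.15 Hz ordinate is
#' shared). The Lomb estimator works directly on the irregular beat times, so
#' no tachogram resampling is needed on 30-s windows.
#'
#' @param times Time stamps of the intervals, seconds (later beat of each
#'   interval).
#' @param intervals RR intervals in seconds; at least 8, spanning >= 25 s.
#' @return Named numeric vector `c(lf, hf)`, both >= 0; `c(0, 0)` for a
#'   zero-variance segment.
#' @export
band_powers <- function(times, intervals) {
  stop_if(length(intervals) != length(times), "times and intervals must align")
  stop_if(length(intervals) < 8L, "band powers need at least 8 intervals")
  stop_if(diff(range(times)) < 25, "band powers need a span of at least 25 s")
  if (pop_var(intervals) == 0) return(c(lf = 0, hf = 0))
  lf_grid <- seq(LF_BAND[1], LF_BAND[2], by = FREQ_STEP)
  hf_grid <- seq(HF_BAND[1], HF_BAND[2], by = FREQ_STEP)
  p_lf <- lomb_psd(times, intervals, lf_grid)
  p_hf <- lomb_psd(times, intervals, hf_grid)
  c(lf = trapz(lf_grid, p_lf), hf = trapz(hf_grid, p_hf))
}

#' Normalized spectral powers and the LF/HF ratio
#'
#' LFn = LF/(LF+HF), HFn = HF/(LF+HF) (so LFn + HFn = 1), LF_HF = LF/HF.
#' Degenerate inputs are imputed neutrally so the pipeline never emits
#' non-finite values: both powers zero gives (0.5, 0.5, 1); HF = 0 < LF caps
#' the ratio at `ratio_cap`.
#'
#' @param lf,hf Non-negative band powers.
#' @param ratio_cap Ceiling for LF/HF when HF is zero.
#' @return Named numeric vector `c(LFn, HFn, LF_HF)`.
#' @export
normalized_spectra <- function(lf, hf, ratio_cap = 100) {
  stop_if(lf < 0 || hf < 0, "band powers must be non-negative")
  if (lf + hf == 0) return(c(LFn = 0.5, HFn = 0.5, LF_HF = 1))
  ratio <- if (hf == 0) ratio_cap else min(lf / hf, ratio_cap)
  c(LFn = lf / (lf + hf), HFn = hf / (lf + hf), LF_HF = ratio)
}

#' Approximate entropy
#'
#' ApEn(m, r) = Phi_m(r) - Phi_(m+1)(r), where
#' Phi_m(r) = mean over templates i of log C_i^m(r) and C_i^m(r) is the
#' fraction of length-m templates within Chebyshev distance r of template i
#' (self-matches included; the standard Pincus definition). Low values mean a
#' regular, predictable series.
#'
#' @param intervals RR intervals in seconds, length n > m + 1.
#' @param m Embedding (template) length, default 2.
#' @param r Tolerance in seconds; default `0.2 * SD` of the segment
#'   (population SD). Must be > 0; a zero-variance segment returns 0.
#' @return Approximate entropy in nats, >= 0 up to floating tolerance.
#' @export
apen <- function(intervals, m = 2L, r = NULL) {
  n <- length(intervals)
  stop_if(n <= m + 1L, "apen needs more than m + 1 intervals")
  if (is.null(r)) {
    s <- pop_sd(intervals)
    if (s == 0) return(0)
    r <- 0.2 * s
  }
  stop_if(r <= 0, "tolerance r must be positive")
  phi <- function(mm) {
    n_tpl <- n - mm + 1L
    # embedding matrix: row i = template starting at i
    emb <- sapply(seq_len(mm), function(j) intervals[j:(j + n_tpl - 1L)])
    emb <- matrix(emb, nrow = n_tpl)
    counts <- vapply(seq_len(n_tpl), function(i) {
      d <- abs(emb - rep(emb[i, ], each = n_tpl))
      cheb <- if (mm == 1L) d[, 1L] else apply(d, 1L, max)
      sum(cheb <= r)
    }, numeric(1))
    mean(log(counts / n_tpl))
  }
  phi(m) - phi(m + 1L)
}

#' Poincare SD1/SD2 ratio
#'
#' From the lagged point cloud (RR_k, RR_(k+1)): SD1 is the dispersion along
#' the minor (-45 degree) axis, `sd((RR_(k+1) - RR_k)/sqrt(2))`, and SD2 along
#' the major (+45 degree) axis, `sd((RR_(k+1) + RR_k)/sqrt(2))` (population
#' SDs). Returns the SD ratio by default; set `variance_ratio = TRUE` for
#' SD1^2/SD2^2.
#'
#' @param intervals RR intervals in seconds (>= 3).
#' @param variance_ratio Return the ratio of variances instead of SDs.
#' @return SD1/SD2 (dimensionless, >= 0).
#' @export
poincare_ratio <- function(intervals, variance_ratio = FALSE) {
  n <- length(intervals)
  stop_if(n < 3L, "poincare_ratio needs at least 3 intervals")
  a <- intervals[-n]
  b <- intervals[-1L]
  sd1 <- pop_sd((b - a) / sqrt(2))
  sd2 <- pop_sd((b + a) / sqrt(2))
  stop_if(sd2 == 0, "degenerate Poincare cloud: SD2 is zero")
  if (variance_ratio) sd1^2 / sd2^2 else sd1 / sd2
}

#' Seven-feature HRV vector for one window
#'
#' Fixed slot order `mRR, SDNN, HFn, LFn, LF_HF, ApEn, SD1_SD2`. Degenerate
#' (zero-variance) windows are imputed neutrally: band powers 0 (hence
#' LFn = HFn = 0.5, LF/HF = 1), ApEn 0, SD1/SD2 0.
#'
#' @param times Time stamps of the intervals (seconds).
#' @param intervals RR intervals (seconds); at least 8 spanning >= 25 s.
#' @param apen_m,apen_r ApEn parameters (defaults m = 2, r = 0.2 SD).
#' @param ratio_cap Cap for LF/HF when HF is zero.
#' @return Named numeric vector of length 7, all finite.
#' @export
feature_vector <- function(times, intervals, apen_m = 2L, apen_r = NULL,
                           ratio_cap = 100) {
  bp <- band_powers(times, intervals)
  ns <- normalized_spectra(bp[["lf"]], bp[["hf"]], ratio_cap = ratio_cap)
  sd12 <- if (pop_var(intervals[-length(intervals)] + intervals[-1L]) == 0) 0
          else poincare_ratio(intervals)
  out <- c(
    mRR = mean_rr(intervals),
    SDNN = sdnn(intervals),
    HFn = unname(ns["HFn"]),
    LFn = unname(ns["LFn"]),
    LF_HF = unname(ns["LF_HF"]),
    ApEn = apen(intervals, m = apen_m, r = apen_r),
    SD1_SD2 = sd12
  )
  stopifnot(all(is.finite(out)))
  out
}
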