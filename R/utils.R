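# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# Derive a per-stream seed from a base seed and small integer tags.
# Kept below 2^31 - 1 so set.seed() always accepts it.
#' @noRd
derive_seed <- function(base, ...) {
  tags <- c(...)
  s <- as.double(base %% 2147483647L)
  for (t in tags) {
    s <- (s * 69069 + as.double(t) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

# Trapezoidal integration on an ordered grid.
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Population variance / sd (divide by n, not n - 1).
#' @noRd
pop_var <- function(x) mean((x - mean(x))^2)

#' @noRd
pop_sd <- function(x) sqrt(pop_var(x))

#' @noRd
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

#' @noRd
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
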