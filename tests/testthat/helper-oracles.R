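# Independent brute-force oracles, written straight from the defining
# formulas as scalar loops. They deliberately share no code with the package
# implementations they check.

# Approximate entropy by exhaustive O(n^2) template counting
# (Pincus definition, self-matches included).
apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    n_tpl <- n - mm + 1
    logs <- numeric(n_tpl)
    for (i in 1:n_tpl) {
      cnt <- 0
      for (j in 1:n_tpl) {
        dmax <- 0
        for (k in 0:(mm - 1)) {
          d <- abs(x[i + k] - x[j + k])
          if (d > dmax) dmax <- d
        }
        if (dmax <= r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / n_tpl)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Poincare SD1/SD2 by explicitly rotating the lagged point cloud by -45
# degrees and taking population SDs along the rotated axes.
poincare_oracle <- function(x) {
  n <- length(x)
  pts <- cbind(x[1:(n - 1)], x[2:n])
  theta <- -pi / 4
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rotated <- pts %*% rot
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  # rotating by -45 degrees maps the identity (major) axis onto the y axis
  sd1 <- psd(rotated[, 1])  # minor (-45 degree) axis
  sd2 <- psd(rotated[, 2])  # major (+45 degree) axis
  sd1 / sd2
}

# Population SD via an explicit loop.
sdnn_oracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  acc <- 0
  for (i in 1:n) acc <- acc + (x[i] - mu)^2
  sqrt(acc / n)
}

# Classic Lomb periodogram evaluated one frequency at a time with scalar
# sums, then trapezoid-integrated over the LF/HF bands.
lomb_band_oracle <- function(times, values) {
  y <- values - sum(values) / length(values)
  pow_at <- function(f) {
    w <- 2 * pi * f
    s2 <- 0; c2 <- 0
    for (t in times) { s2 <- s2 + sin(2 * w * t); c2 <- c2 + cos(2 * w * t) }
    tau <- atan2(s2, c2) / (2 * w)
    yc <- 0; ys <- 0; cc <- 0; ss <- 0
    for (i in seq_along(times)) {
      ct <- cos(w * (times[i] - tau)); st <- sin(w * (times[i] - tau))
      yc <- yc + y[i] * ct; ys <- ys + y[i] * st
      cc <- cc + ct^2; ss <- ss + st^2
    }
    0.5 * (yc^2 / cc + ys^2 / ss)
  }
  band <- function(lo, hi) {
    grid <- seq(lo, hi, by = 0.002)
    p <- vapply(grid, pow_at, numeric(1))
    acc <- 0
    for (i in 2:length(grid)) {
      acc <- acc + (grid[i] - grid[i - 1]) * (p[i] + p[i - 1]) / 2
    }
    acc
  }
  c(lf = band(0.04, 0.15), hf = band(0.15, 0.40))
}

# One GRU cell step, scalar loops straight from the gate equations.
gru_cell_oracle <- function(x, h, p) {
  H <- length(h)
  I <- length(x)
  sig <- function(v) 1 / (1 + exp(-v))
  r <- numeric(H); z <- numeric(H); cc <- numeric(H); hn <- numeric(H)
  for (j in 1:H) {
    ar <- p$b_r[j]; az <- p$b_z[j]
    for (i in 1:I) { ar <- ar + x[i] * p$W_ir[i, j]; az <- az + x[i] * p$W_iz[i, j] }
    for (i in 1:H) { ar <- ar + h[i] * p$W_hr[i, j]; az <- az + h[i] * p$W_hz[i, j] }
    r[j] <- sig(ar); z[j] <- sig(az)
  }
  for (j in 1:H) {
    ac <- p$b_c[j]
    for (i in 1:I) ac <- ac + x[i] * p$W_ic[i, j]
    for (i in 1:H) ac <- ac + r[i] * h[i] * p$W_hc[i, j]
    cc[j] <- tanh(ac)
  }
  for (j in 1:H) hn[j] <- (1 - z[j]) * cc[j] + z[j] * h[j]
  hn
}

# Stacked layers over a sequence, composed from the cell oracle
# (zero initial hidden state per layer).
gru_stack_oracle <- function(inputs, layers) {
  seq_in <- inputs
  for (p in layers) {
    h <- numeric(ncol(p$W_ir))
    outs <- vector("list", length(seq_in))
    for (n in seq_along(seq_in)) {
      h <- gru_cell_oracle(seq_in[[n]], h, p)
      outs[[n]] <- h
    }
    seq_in <- outs
  }
  seq_in
}

# Random cell parameters for small instances.
random_cell <- function(in_dim, h) {
  rm_ <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.5), nr, nc)
  list(W_ir = rm_(in_dim, h), W_hr = rm_(h, h), b_r = stats::rnorm(h, sd = 0.3),
       W_iz = rm_(in_dim, h), W_hz = rm_(h, h), b_z = stats::rnorm(h, sd = 0.3),
       W_ic = rm_(in_dim, h), W_hc = rm_(h, h), b_c = stats::rnorm(h, sd = 0.3))
}

# Random RR-like segment whose intervals sum to `span` seconds exactly
# (n is raised if needed so no interval exceeds physiologic magnitudes).
random_segment <- function(n, span = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- max(n, ceiling(span / 1.5))
  iv <- stats::runif(n, 0.6, 1.0)
  iv <- iv * span / sum(iv)
  list(times = cumsum(iv), intervals = iv)
}

# Directly constructed, linearly separable "HRV-like" samples: class k gets a
# distinct base pattern plus small noise. Used to test the learning machinery
# without the RR pipeline.
make_blob_samples <- function(n_subjects, N = 6, noise = 0.03, seed = 1) {
  set.seed(seed)
  base <- lapply(1:4, function(k) {
    matrix(0.2 * k + 0.1 * sin(seq_len(N) + k), N, 7) +
      matrix(stats::runif(N * 7, -0.1, 0.1), N, 7)
  })
  out <- list()
  for (s in seq_len(n_subjects)) {
    for (k in 1:4) {
      vals <- base[[k]] + matrix(stats::rnorm(N * 7, 0, noise), N, 7)
      colnames(vals) <- hrv_feature_names()
      out[[length(out) + 1L]] <- structure(
        list(values = vals, label = k, subject_id = s),
        class = "sample_matrix")
    }
  }
  out
}
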