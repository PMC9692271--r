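# GRU cell/block forward pass, classification head, and the loss.

test_that("a saturated update gate freezes the hidden state exactly", {
  h <- 4L
  cp <- list(W_ir = matrix(0, 3, h), W_hr = matrix(0, h, h), b_r = rep(0, h),
             W_iz = matrix(0, 3, h), W_hz = matrix(0, h, h), b_z = rep(50, h),
             W_ic = matrix(0, 3, h), W_hc = matrix(0, h, h), b_c = rep(0, h))
  h_prev <- c(0.3, -0.2, 0.8, 0.1)
  expect_identical(gru_cell_step(c(1, -1, 2), h_prev, cp), h_prev)
})

test_that("all-zero parameters halve the hidden state exactly", {
  h <- 3L
  cp <- list(W_ir = matrix(0, 2, h), W_hr = matrix(0, h, h), b_r = rep(0, h),
             W_iz = matrix(0, 2, h), W_hz = matrix(0, h, h), b_z = rep(0, h),
             W_ic = matrix(0, 2, h), W_hc = matrix(0, h, h), b_c = rep(0, h))
  h_prev <- c(0.5, -0.25, 1)
  expect_identical(gru_cell_step(c(2, 3), h_prev, cp), 0.5 * h_prev)
})

test_that("the cell matches the scalar-loop oracle", {
  set.seed(31)
  for (i in 1:20) {
    in_dim <- sample(1:4, 1); h <- sample(1:4, 1)
    cp <- random_cell(in_dim, h)
    x <- rnorm(in_dim); h0 <- rnorm(h)
    expect_equal(gru_cell_step(x, h0, cp), gru_cell_oracle(x, h0, cp),
                 tolerance = 1e-10)
  }
})

test_that("cell output is elementwise between the candidate and previous state", {
  set.seed(32)
  for (i in 1:20) {
    cp <- random_cell(3, 4)
    h0 <- rnorm(4)
    out <- gru_cell_step(rnorm(3), h0, cp)
    expect_true(all(abs(out) <= pmax(abs(h0), 1) + 1e-12))
  }
})

test_that("a one-layer one-step block equals a single cell from zero state", {
  set.seed(33)
  cp <- random_cell(3, 5)
  x <- rnorm(3)
  blk <- gru_block_forward(list(x), list(cp))
  expect_equal(drop(blk$last_output), gru_cell_step(x, numeric(5), cp),
               tolerance = 1e-14)
})

test_that("frozen gates keep a block's output at the zero initial state", {
  h <- 3L
  frozen <- function(in_dim) {
    list(W_ir = matrix(0, in_dim, h), W_hr = matrix(0, h, h), b_r = rep(0, h),
         W_iz = matrix(0, in_dim, h), W_hz = matrix(0, h, h), b_z = rep(50, h),
         W_ic = matrix(0, in_dim, h), W_hc = matrix(0, h, h), b_c = rep(0, h))
  }
  inputs <- replicate(4, rnorm(2), simplify = FALSE)
  blk <- gru_block_forward(inputs, list(frozen(2L), frozen(h)))
  expect_equal(drop(blk$last_output), numeric(3))
})

test_that("stacked blocks match the composed oracle", {
  set.seed(34)
  for (i in 1:10) {
    K <- sample(1:2, 1); N <- sample(2:5, 1); h <- sample(2:4, 1)
    layers <- c(list(random_cell(3, h)),
                replicate(K - 1, random_cell(h, h), simplify = FALSE))
    inputs <- replicate(N, rnorm(3), simplify = FALSE)
    got <- gru_block_forward(inputs, layers)
    want <- gru_stack_oracle(inputs, layers)
    for (n in seq_len(N)) {
      expect_equal(drop(got$per_step[[n]]), want[[n]], tolerance = 1e-10)
    }
  }
})

test_that("the full forward matches the oracle through both cascaded blocks", {
  set.seed(35)
  cfg <- model_config(n_blocks = 2, layers_per_block = 2, hidden_units = 3,
                      seq_len = 4, head_sizes = c(5, 4, 4))
  m <- init_model(cfg, seed = 3)
  x <- matrix(runif(4 * 7), 4, 7)
  pred <- model_forward(m, x)
  inputs <- lapply(1:4, function(n) x[n, ])
  l1 <- lapply(1:2, function(l) hrvstress:::cell_params_at(m$params, 1, l))
  l2 <- lapply(1:2, function(l) hrvstress:::cell_params_at(m$params, 2, l))
  o1 <- gru_stack_oracle(inputs, l1)
  o2 <- gru_stack_oracle(o1, l2)
  expect_equal(unname(pred$deep_feature), c(o1[[4]], o2[[4]]),
               tolerance = 1e-10)
})

test_that("probabilities are a valid simplex point for any weights", {
  cfg <- model_config(n_blocks = 2, layers_per_block = 1, hidden_units = 4,
                      seq_len = 3)
  m <- init_model(cfg, seed = 11)
  x <- matrix(rnorm(3 * 7), 3, 7)
  p <- model_forward(m, x)$probabilities
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  expect_equal(model_forward(m, x)$predicted_label, which.max(p))
})

test_that("inference is deterministic: identical samples, identical output", {
  cfg <- model_config(n_blocks = 2, layers_per_block = 1, hidden_units = 4,
                      seq_len = 3)
  m <- init_model(cfg, seed = 12)
  x <- matrix(rnorm(3 * 7), 3, 7)
  expect_identical(model_forward(m, x), model_forward(m, x))
})

test_that("a single block yields a deep feature of width hidden_units", {
  cfg <- model_config(n_blocks = 1, layers_per_block = 2, hidden_units = 5,
                      seq_len = 3)
  m <- init_model(cfg, seed = 13)
  f <- model_forward(m, matrix(rnorm(21), 3, 7))$deep_feature
  expect_length(f, 5L)
})

test_that("softmax is invariant to constant logit shifts", {
  set.seed(36)
  z <- matrix(rnorm(8), 2, 4)
  expect_equal(softmax(z), softmax(z + 123.4), tolerance = 1e-6)
})

test_that("loss closed forms", {
  perfect <- diag(4)[c(1, 2, 3, 4), ]
  expect_equal(model_loss(perfect, 1:4), 0, tolerance = 1e-10)
  unif <- matrix(0.25, 3, 4)
  expect_equal(model_loss(unif, c(1, 4, 2)), log(4), tolerance = 1e-9)
  params <- list(`head1.W` = matrix(0, 2, 2), `head1.b` = c(1, 1))
  expect_equal(model_loss(unif, c(1, 4, 2), params, gamma = 0.5), log(4),
               tolerance = 1e-9)
  params$`head1.W`[] <- 2
  expect_equal(model_loss(unif, c(1, 4, 2), params, gamma = 0.5),
               log(4) + 0.5 * 16, tolerance = 1e-9)
  expect_error(model_loss(unif[0, , drop = FALSE], integer(0)), "empty")
})

test_that("analytic gradients match finite differences", {
  set.seed(37)
  cfg <- model_config(n_blocks = 2, layers_per_block = 2, hidden_units = 3,
                      seq_len = 4, head_sizes = c(5, 4, 4))
  m <- init_model(cfg, seed = 9)
  x <- array(runif(3 * 4 * 7), dim = c(3, 4, 7))
  y <- c(1L, 3L, 4L)
  gamma <- 0.01
  fw <- hrvstress:::forward_pass(m, x, training = TRUE, keep_cache = TRUE)
  g <- hrvstress:::backward_pass(m, fw, y, gamma)
  lossfun <- function(mm) {
    f <- hrvstress:::forward_pass(mm, x, training = TRUE)
    model_loss(f$probs, y, mm$params, gamma)
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    for (i in seq_len(min(length(m$params[[nm]]), 3))) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm2 <- m; mm2$params[[nm]][i] <- mm2$params[[nm]][i] - eps
      num <- (lossfun(mp) - lossfun(mm2)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad[%s][%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip with config and batch-norm state", {
  dir <- withr::local_tempdir()
  m <- init_model(model_config(n_blocks = 1, layers_per_block = 1,
                               hidden_units = 3, seq_len = 3), seed = 2)
  p <- file.path(dir, "model.rds")
  save_model(m, p)
  back <- load_model(p)
  x <- matrix(rnorm(21), 3, 7)
  expect_identical(model_forward(back, x), model_forward(m, x))
})
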