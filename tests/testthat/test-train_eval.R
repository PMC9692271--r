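# Cross-subject splitting, training behavior, evaluation, repeats.

small_model <- function() {
  model_config(n_blocks = 2, layers_per_block = 1, hidden_units = 8,
               seq_len = 6)
}

test_that("the study-shaped split leaves 16 test subjects", {
  sp <- split_cohort(1:63, n_train = 47, n_val = 8, seed = 1)
  expect_length(sp$train, 39L)
  expect_length(sp$val, 8L)
  expect_length(sp$test, 16L)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:63)
})

test_that("splits are seeded, subject-level and disjoint", {
  expect_identical(split_cohort(1:63, 47, 8, seed = 5),
                   split_cohort(1:63, 47, 8, seed = 5))
  expect_false(identical(split_cohort(1:63, 47, 8, seed = 5),
                         split_cohort(1:63, 47, 8, seed = 6)))
  sp0 <- split_cohort(1:10, n_train = 7, n_val = 0, seed = 2)
  expect_length(sp0$val, 0L)
  for (s in 1:10) {
    sp <- split_cohort(1:21, n_train = 12, n_val = 3, seed = s)
    expect_equal(anyDuplicated(c(sp$train, sp$val, sp$test)), 0L)
  }
  expect_error(split_cohort(1:10, n_train = 10, n_val = 2), "below")
  expect_error(split_cohort(1:10, n_train = 5, n_val = 5), "below")
})

test_that("evaluation: perfect, constant and hand-built predictions", {
  r <- eval_report(pred = c(1, 2, 3, 4, 1, 2, 3, 4),
                   truth = c(1, 2, 3, 4, 1, 2, 3, 4))
  expect_equal(r$accuracy, 1)
  expect_equal(r$confusion, diag(4), ignore_attr = TRUE)

  const <- eval_report(pred = rep(2, 8), truth = rep(1:4, each = 2))
  expect_equal(const$accuracy, 0.25)

  hand <- eval_report(pred = c(1, 4, 2, 2, 3, 3, 4, 1),
                      truth = c(1, 1, 2, 2, 3, 4, 4, 4))
  expect_equal(hand$accuracy, 5 / 8)
  expect_equal(hand$confusion[1, ], c(0.5, 0, 0, 0.5), ignore_attr = TRUE)
  expect_equal(hand$confusion[2, ], c(0, 1, 0, 0), ignore_attr = TRUE)
  expect_equal(hand$confusion[3, ], c(0, 0, 1, 0), ignore_attr = TRUE)
  expect_equal(hand$confusion[4, ], c(1 / 3, 0, 1 / 3, 1 / 3),
               ignore_attr = TRUE)
  expect_error(eval_report(integer(0), integer(0)), "non-empty")
})

test_that("confusion rows sum to one and accuracy is the balanced recall mean", {
  set.seed(41)
  pred <- sample(1:4, 40, replace = TRUE)
  truth <- rep(1:4, each = 10)  # exactly balanced
  r <- eval_report(pred, truth)
  expect_equal(rowSums(r$confusion), rep(1, 4), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(r$accuracy, mean(diag(r$confusion)), tolerance = 1e-12)
  expect_gte(r$accuracy, 0)
  expect_lte(r$accuracy, 1)
})

test_that("zero learning rate leaves the weights unchanged", {
  samples <- make_blob_samples(4, seed = 42)
  st <- stack_samples(standardize(samples, fit_standardizer(samples)))
  m0 <- init_model(small_model(), seed = 1)
  # one full batch per epoch so the training-mode loss is comparable across
  # epochs (batch-norm running statistics are state and may still evolve)
  tc <- train_config(lr = 0, batch_size = 16, epochs = 2, l2_gamma = 0,
                     repeats = 1)
  m1 <- train_model(m0, st$x, st$y, tc, seed = 4)
  expect_equal(m1$params, m0$params, tolerance = 1e-14)
  expect_equal(m1$history$loss[1], m1$history$loss[2], tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  samples <- make_blob_samples(4, seed = 43)
  st <- stack_samples(standardize(samples, fit_standardizer(samples)))
  tc <- train_config(lr = 0.005, batch_size = 8, epochs = 3, repeats = 1)
  m0 <- init_model(small_model(), seed = 7)
  a <- train_model(m0, st$x, st$y, tc, seed = 9)
  b <- train_model(m0, st$x, st$y, tc, seed = 9)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("loss decreases on linearly separable features", {
  samples <- make_blob_samples(6, seed = 44)
  st <- stack_samples(standardize(samples, fit_standardizer(samples)))
  tc <- train_config(lr = 0.01, batch_size = 8, epochs = 20, repeats = 1)
  m <- train_model(init_model(small_model(), seed = 3), st$x, st$y, tc,
                   seed = 5)
  expect_lt(mean(tail(m$history$loss, 2)), m$history$loss[1])
  expect_gte(tail(m$history$train_acc, 1), 0.9)
})

test_that("standardization statistics depend only on the training partition", {
  samples <- make_blob_samples(6, seed = 45)
  subjects <- vapply(samples, `[[`, integer(1), "subject_id")
  sp <- split_cohort(unique(subjects), n_train = 4, n_val = 1, seed = 1)
  train <- samples[subjects %in% sp$train]
  st1 <- fit_standardizer(train)
  # mutate a test-subject sample: training statistics must not move
  idx <- which(subjects %in% sp$test)[1]
  samples[[idx]]$values <- samples[[idx]]$values * 100
  st2 <- fit_standardizer(samples[subjects %in% sp$train])
  expect_identical(st1, st2)
})

test_that("repeat_experiment averages per-repeat accuracies deterministically", {
  samples <- make_blob_samples(8, seed = 46)
  mc <- small_model()
  tc <- train_config(lr = 0.005, batch_size = 8, epochs = 4, repeats = 1,
                     seed_base = 2)
  one <- repeat_experiment(samples, mc, tc, n_train = 6, n_val = 1)
  expect_equal(one$mean_accuracy, one$accuracies[1])
  again <- repeat_experiment(samples, mc, tc, n_train = 6, n_val = 1)
  expect_identical(one$mean_accuracy, again$mean_accuracy)
  tc2 <- train_config(lr = 0.005, batch_size = 8, epochs = 4, repeats = 2,
                      seed_base = 2)
  two <- repeat_experiment(samples, mc, tc2, n_train = 6, n_val = 1)
  expect_equal(two$mean_accuracy, mean(two$accuracies))
  expect_equal(two$accuracies[1], one$accuracies[1])
})

test_that("every subject's samples land in exactly one partition", {
  samples <- make_blob_samples(8, seed = 47)
  res <- run_experiment(samples, small_model(),
                        train_config(lr = 0.005, batch_size = 8, epochs = 2,
                                     repeats = 1),
                        n_train = 6, n_val = 1, seed = 3)
  sp <- res$split
  expect_equal(anyDuplicated(c(sp$train, sp$val, sp$test)), 0L)
  expect_length(c(sp$train, sp$val, sp$test), 8L)
  expect_true(res$report$accuracy >= 0 && res$report$accuracy <= 1)
})
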