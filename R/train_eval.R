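# Cross-subject splitting, evaluation (accuracy + row-normalized confusion
# matrix), and repeated-experiment averaging.

#' Cross-subject train/validation/test split
#'
#' Subjects (never individual samples) are shuffled with the given seed;
#' `n_train` go to the training pool, of which `n_val` are moved to the
#' validation set; the remainder form the test set. With the emulated study
#' shape (63 subjects, 47 train incl. 8 validation) this leaves 16 test
#' subjects.
#'
#' @param subject_ids Vector of unique subject identifiers.
#' @param n_train Subjects in the training pool (validation included).
#' @param n_val Subjects moved from the pool to the validation set.
#' @param seed Integer seed.
#' @return A `split_spec`: list of disjoint `train`, `val`, `test` id vectors.
#' @export
split_cohort <- function(subject_ids, n_train = 47L, n_val = 8L, seed = 1L) {
  subject_ids <- unique(subject_ids)
  total <- length(subject_ids)
  stop_if(!is_count(n_train) || n_train >= total,
          "n_train must be a positive count below the number of subjects")
  stop_if(!is_count(n_val, min = 0L) || n_val >= n_train,
          "n_val must be a count below n_train")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  shuffled <- sample(subject_ids)
  pool <- shuffled[seq_len(n_train)]
  val <- if (n_val > 0L) sample(pool, n_val) else pool[0L]
  spec <- structure(
    list(train = setdiff(pool, val), val = val,
         test = shuffled[(n_train + 1L):total]),
    class = "split_spec"
  )
  stopifnot(!anyDuplicated(c(spec$train, spec$val, spec$test)))
  spec
}

#' Evaluate predictions on a test set
#'
#' Accuracy is the fraction of correctly classified samples (the class counts
#' are balanced by construction, so plain accuracy is the headline metric).
#' The confusion matrix is row-normalized: entry (i, j) is the proportion of
#' true-class-i samples predicted as class j.
#'
#' @param model A trained `stress_model`.
#' @param x Test samples, M x N x 7 array standardized with *training*
#'   statistics.
#' @param y True labels 1..4.
#' @return An `eval_report`: list with `accuracy`, `confusion` (4 x 4
#'   row-normalized), `n`.
#' @export
evaluate_model <- function(model, x, y) {
  stop_if(!length(y), "empty test set")
  pred <- model_forward(model, x)$predicted_label
  eval_report(pred, y)
}

#' Build an evaluation report from predicted and true labels
#'
#' @param pred,truth Integer labels 1..4.
#' @return An `eval_report`.
#' @export
eval_report <- function(pred, truth) {
  stop_if(length(pred) != length(truth) || !length(truth),
          "pred and truth must be equal-length, non-empty")
  conf <- matrix(0, 4L, 4L, dimnames = list(true = 1:4, predicted = 1:4))
  for (k in 1:4) {
    nk <- sum(truth == k)
    if (nk > 0) {
      conf[k, ] <- tabulate(pred[truth == k], nbins = 4L) / nk
    }
  }
  structure(list(accuracy = mean(pred == truth), confusion = conf,
                 n = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f on %d samples\n", x$accuracy, x$n))
  print(round(x$confusion, 2))
  invisible(x)
}

#' @noRd
subset_stack <- function(stacked, subjects) {
  keep <- stacked$subjects %in% subjects
  list(x = stacked$x[keep, , , drop = FALSE], y = stacked$y[keep],
       subjects = stacked$subjects[keep])
}

#' Run one cross-subject experiment
#'
#' Splits subjects, fits the min-max standardizer on the training partition
#' only, standardizes all partitions with those statistics, trains the model,
#' and evaluates on the held-out subjects.
#'
#' @param samples List of (raw, unstandardized) `sample_matrix` objects.
#' @param mconfig A [model_config].
#' @param tconfig A [train_config].
#' @param n_train,n_val Subjects in the training pool / validation subset.
#' @param seed Seed controlling the split, weight initialization and batch
#'   shuffling for this run.
#' @return List with `model`, `report` ([eval_report]), `split`, `stats`.
#' @export
run_experiment <- function(samples, mconfig = model_config(),
                           tconfig = train_config(), n_train = 47L,
                           n_val = 8L, seed = 1L) {
  subjects <- unique(vapply(samples, function(s) as.integer(s$subject_id),
                            integer(1)))
  split <- split_cohort(subjects, n_train = n_train, n_val = n_val, seed = seed)

  is_train <- vapply(samples, function(s) s$subject_id %in% split$train,
                     logical(1))
  stats <- fit_standardizer(samples[is_train])
  std <- standardize(samples, stats)
  stacked <- stack_samples(std)

  tr <- subset_stack(stacked, split$train)
  va <- subset_stack(stacked, split$val)
  te <- subset_stack(stacked, split$test)

  model <- init_model(mconfig, seed = derive_seed(seed, 1L))
  model <- train_model(model, tr$x, tr$y, tconfig,
                       val_x = if (length(va$y)) va$x else NULL,
                       val_y = if (length(va$y)) va$y else NULL,
                       seed = derive_seed(seed, 2L))
  report <- evaluate_model(model, te$x, te$y)
  list(model = model, report = report, split = split, stats = stats)
}

#' Repeated cross-subject experiments
#'
#' Runs [run_experiment()] with consecutive seeds
#' `seed_base, ..., seed_base + repeats - 1` (each repeat re-draws the subject
#' split and the weight initialization) and averages the test accuracies into
#' the final evaluation index.
#'
#' @param samples List of raw `sample_matrix` objects.
#' @param mconfig,tconfig Model / training configuration.
#' @param n_train,n_val Split sizes (subjects).
#' @return List with `mean_accuracy`, `accuracies` (per repeat), `reports`.
#' @export
repeat_experiment <- function(samples, mconfig = model_config(),
                              tconfig = train_config(), n_train = 47L,
                              n_val = 8L) {
  seeds <- tconfig$seed_base + seq_len(tconfig$repeats) - 1L
  runs <- lapply(seeds, function(s) {
    run_experiment(samples, mconfig, tconfig, n_train = n_train,
                   n_val = n_val, seed = s)
  })
  acc <- vapply(runs, function(r) r$report$accuracy, numeric(1))
  list(mean_accuracy = mean(acc), accuracies = acc,
       reports = lapply(runs, `[[`, "report"))
}

#' Write an evaluation report and training curves to disk
#'
#' @param report An [eval_report].
#' @param history Training history data frame (from a trained model), or
#'   `NULL`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, history = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jpath <- file.path(dir, "eval_report.json")
  jsonlite::write_json(
    list(accuracy = report$accuracy, n = report$n,
         confusion = report$confusion),
    jpath, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  cpath <- file.path(dir, "confusion.csv")
  utils::write.csv(as.data.frame(report$confusion), cpath)
  paths <- c(jpath, cpath)
  if (!is.null(history)) {
    hpath <- file.path(dir, "curves.csv")
    utils::write.csv(history, hpath, row.names = FALSE)
    paths <- c(paths, hpath)
  }
  invisible(paths)
}
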