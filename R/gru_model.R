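# Stacked-GRU deep feature extractor and fully connected softmax head.
#
# Gate equations per cell (biases folded into each affine map):
#   r_n = sigmoid(W_ir x_n + W_hr h_{n-1})
#   z_n = sigmoid(W_iz x_n + W_hz h_{n-1})
#   c_n = tanh(W_ic x_n + W_hc (r_n . h_{n-1}))
#   h_n = (1 - z_n) . c_n + z_n . h_{n-1}
# The feature extractor cascades `n_blocks` GRU blocks (each K stacked
# layers); block b+1 consumes block b's per-step outputs. The concatenated
# last-step outputs of all blocks feed a 64-32-4 fully connected head with
# batch normalization and ReLU between layers and a softmax output.

#' Model configuration
#'
#' Defaults mirror the full-scale architecture: 2 cascaded blocks of 5 GRU
#' layers with 256 units each, 20 time steps of 7 HRV features, and a
#' 64-32-4 fully connected head.
#'
#' @param n_blocks Number of cascaded GRU blocks.
#' @param layers_per_block GRU layers (K) stacked inside each block.
#' @param hidden_units Hidden width of every GRU layer.
#' @param seq_len Time steps per sample (N).
#' @param input_dim Features per time step (7 HRV features).
#' @param head_sizes Fully connected layer widths; the last entry must be 4
#'   (the four stress classes).
#' @param l2_gamma Default L2 regularization coefficient for training.
#' @return A `model_config` list.
#' @export
model_config <- function(n_blocks = 2L, layers_per_block = 5L,
                         hidden_units = 256L, seq_len = 20L, input_dim = 7L,
                         head_sizes = c(64L, 32L, 4L), l2_gamma = 0.002) {
  stop_if(!is_count(n_blocks) || !is_count(layers_per_block) ||
            !is_count(hidden_units) || !is_count(seq_len) ||
            !is_count(input_dim), "all size fields must be positive integers")
  stop_if(utils::tail(head_sizes, 1L) != 4L,
          "the head must end in 4 output classes")
  stop_if(l2_gamma < 0, "l2_gamma must be >= 0")
  structure(list(n_blocks = as.integer(n_blocks),
                 layers_per_block = as.integer(layers_per_block),
                 hidden_units = as.integer(hidden_units),
                 seq_len = as.integer(seq_len),
                 input_dim = as.integer(input_dim),
                 head_sizes = as.integer(head_sizes),
                 l2_gamma = l2_gamma),
            class = "model_config")
}

#' @noRd
add_bias <- function(M, b) M + rep(b, each = nrow(M))

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Logistic and softmax activations
#'
#' `softmax` is row-wise and max-stabilized, so it is invariant to adding a
#' constant to all logits of a sample.
#' @param z Numeric matrix of logits (rows = samples).
#' @return Matrix of probabilities, rows summing to 1.
#' @export
softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' One GRU cell step
#'
#' Applies the gate equations to one time step. Accepts a single input vector
#' with a single hidden-state vector, or batch matrices (rows = batch).
#'
#' @param x Input vector (length `in_dim`) or matrix (B x in_dim).
#' @param h_prev Previous hidden state, vector (length `h`) or matrix (B x h).
#' @param params List with `W_ir`, `W_hr`, `b_r`, `W_iz`, `W_hz`, `b_z`,
#'   `W_ic`, `W_hc`, `b_c`; input matrices are `in_dim x h`, hidden matrices
#'   `h x h`.
#' @return New hidden state, same shape as `h_prev`.
#' @export
gru_cell_step <- function(x, h_prev, params) {
  vec_in <- is.null(dim(x))
  if (vec_in) {
    x <- matrix(x, nrow = 1L)
    h_prev <- matrix(h_prev, nrow = 1L)
  }
  stop_if(ncol(x) != nrow(params$W_ir) || ncol(h_prev) != nrow(params$W_hr),
          "dimension mismatch between inputs and cell parameters")
  r <- sigmoid(add_bias(x %*% params$W_ir + h_prev %*% params$W_hr, params$b_r))
  z <- sigmoid(add_bias(x %*% params$W_iz + h_prev %*% params$W_hz, params$b_z))
  c_ <- tanh(add_bias(x %*% params$W_ic + (r * h_prev) %*% params$W_hc, params$b_c))
  h <- (1 - z) * c_ + z * h_prev
  if (vec_in) drop(h) else h
}

#' Forward pass through one GRU block
#'
#' Layer 1 consumes the input sequence; layer k consumes layer k-1's per-step
#' outputs. Hidden states start at zero.
#'
#' @param inputs List of N input matrices (B x in_dim) or vectors.
#' @param layers List of K cell parameter lists (see [gru_cell_step()]).
#' @return List with `per_step` (list of N output matrices of the top layer)
#'   and `last_output` (top layer output at step N).
#' @export
gru_block_forward <- function(inputs, layers) {
  stop_if(!length(inputs), "empty input sequence")
  seq_in <- lapply(inputs, function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else x)
  for (layer in layers) {
    B <- nrow(seq_in[[1L]])
    h <- matrix(0, B, ncol(layer$W_ir))
    out <- vector("list", length(seq_in))
    for (n in seq_along(seq_in)) {
      h <- gru_cell_step(seq_in[[n]], h, layer)
      out[[n]] <- h
    }
    seq_in <- out
  }
  list(per_step = seq_in, last_output = seq_in[[length(seq_in)]])
}

# --- parameter initialization -------------------------------------------------

#' @noRd
init_cell <- function(in_dim, h, runit) {
  list(W_ir = runit(in_dim, h), W_hr = runit(h, h), b_r = numeric(h),
       W_iz = runit(in_dim, h), W_hz = runit(h, h), b_z = numeric(h),
       W_ic = runit(in_dim, h), W_hc = runit(h, h), b_c = numeric(h))
}

#' Initialize a stress classification model
#'
#' All weight matrices are drawn uniformly from
#' `(-1/sqrt(fan), 1/sqrt(fan))` (fan = hidden width for GRU cells, fan-in
#' for head layers); biases start at zero, batch-norm gains at 1.
#'
#' @param config A [model_config].
#' @param seed Integer seed; initialization is reproducible.
#' @return A `stress_model`: list with `config`, `params` (flat named list),
#'   `bn` (running batch-norm statistics).
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))

  h <- config$hidden_units
  params <- list()
  for (b in seq_len(config$n_blocks)) {
    in_dim <- if (b == 1L) config$input_dim else h
    for (l in seq_len(config$layers_per_block)) {
      bound <- 1 / sqrt(h)
      runit <- function(nr, nc) matrix(stats::runif(nr * nc, -bound, bound), nr, nc)
      cell <- init_cell(if (l == 1L) in_dim else h, h, runit)
      for (nm in names(cell)) params[[sprintf("g%d.%d.%s", b, l, nm)]] <- cell[[nm]]
    }
  }
  feat_dim <- config$n_blocks * h
  sizes <- c(feat_dim, config$head_sizes)
  bn <- list()
  for (k in seq_along(config$head_sizes)) {
    bound <- 1 / sqrt(sizes[k])
    params[[sprintf("head%d.W", k)]] <-
      matrix(stats::runif(sizes[k] * sizes[k + 1L], -bound, bound),
             sizes[k], sizes[k + 1L])
    params[[sprintf("head%d.b", k)]] <- numeric(sizes[k + 1L])
    if (k < length(config$head_sizes)) {
      params[[sprintf("bn%d.gamma", k)]] <- rep(1, sizes[k + 1L])
      params[[sprintf("bn%d.beta", k)]] <- numeric(sizes[k + 1L])
      bn[[sprintf("bn%d", k)]] <- list(mean = numeric(sizes[k + 1L]),
                                       var = rep(1, sizes[k + 1L]))
    }
  }
  structure(list(config = config, params = params, bn = bn),
            class = "stress_model")
}

#' @export
print.stress_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<stress_model> %d block(s) x %d GRU layer(s) x %d units, N = %d, head %s (%s parameters)\n",
    cfg$n_blocks, cfg$layers_per_block, cfg$hidden_units, cfg$seq_len,
    paste(cfg$head_sizes, collapse = "-"),
    format(sum(vapply(x$params, length, numeric(1))), big.mark = ",")))
  invisible(x)
}

# Names of parameters whose squared entries enter the L2 penalty: all weight
# matrices; biases and batch-norm parameters are excluded.
#' @noRd
l2_param_names <- function(params) {
  names(params)[grepl("\\.W($|_)", names(params))]
}

#' @noRd
cell_params_at <- function(params, b, l) {
  pick <- function(nm) params[[sprintf("g%d.%d.%s", b, l, nm)]]
  list(W_ir = pick("W_ir"), W_hr = pick("W_hr"), b_r = pick("b_r"),
       W_iz = pick("W_iz"), W_hz = pick("W_hz"), b_z = pick("b_z"),
       W_ic = pick("W_ic"), W_hc = pick("W_hc"), b_c = pick("b_c"))
}

# Full forward pass. `x` is a B x N x input_dim array. Returns probabilities,
# deep features, and (optionally) the caches needed for backpropagation.
# In training mode batch statistics are used for batch norm and the running
# statistics are updated (exponential moving average with `bn_momentum`)
# via the returned `bn` element; bn_momentum = 0 replaces the running
# statistics with this batch's statistics outright (used to re-estimate them
# over the full training set after training).
#' @noRd
forward_pass <- function(model, x, training = FALSE, keep_cache = FALSE,
                         bn_momentum = 0.9) {
  cfg <- model$config
  p <- model$params
  stopifnot(length(dim(x)) == 3L, dim(x)[2] == cfg$seq_len,
            dim(x)[3] == cfg$input_dim)
  B <- dim(x)[1]
  N <- cfg$seq_len
  h <- cfg$hidden_units

  seq_in <- lapply(seq_len(N), function(n) matrix(x[, n, ], nrow = B))
  cache <- if (keep_cache) list(blocks = list()) else NULL
  lasts <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    bl_cache <- list()
    for (l in seq_len(cfg$layers_per_block)) {
      cp <- cell_params_at(p, b, l)
      H <- matrix(0, B, h)
      outs <- vector("list", N)
      if (keep_cache) {
        lc <- list(X = seq_in, Hprev = vector("list", N),
                   r = vector("list", N), z = vector("list", N),
                   c = vector("list", N))
      }
      for (n in seq_len(N)) {
        X <- seq_in[[n]]
        r <- sigmoid(add_bias(X %*% cp$W_ir + H %*% cp$W_hr, cp$b_r))
        z <- sigmoid(add_bias(X %*% cp$W_iz + H %*% cp$W_hz, cp$b_z))
        c_ <- tanh(add_bias(X %*% cp$W_ic + (r * H) %*% cp$W_hc, cp$b_c))
        Hn <- (1 - z) * c_ + z * H
        if (keep_cache) {
          lc$Hprev[[n]] <- H; lc$r[[n]] <- r; lc$z[[n]] <- z; lc$c[[n]] <- c_
        }
        H <- Hn
        outs[[n]] <- H
      }
      if (keep_cache) bl_cache[[l]] <- lc
      seq_in <- outs
    }
    if (keep_cache) cache$blocks[[b]] <- bl_cache
    lasts[[b]] <- seq_in[[N]]
  }
  feat <- do.call(cbind, lasts)

  # fully connected head: FC -> BN -> ReLU for hidden layers, FC -> softmax out
  bn_eps <- 1e-5
  bn_new <- model$bn
  a <- feat
  head_cache <- list()
  n_head <- length(cfg$head_sizes)
  for (k in seq_len(n_head)) {
    W <- p[[sprintf("head%d.W", k)]]
    bb <- p[[sprintf("head%d.b", k)]]
    zk <- add_bias(a %*% W, bb)
    if (k < n_head) {
      key <- sprintf("bn%d", k)
      gamma <- p[[paste0(key, ".gamma")]]
      beta <- p[[paste0(key, ".beta")]]
      if (training) {
        mu <- colMeans(zk)
        v <- colMeans(zk^2) - mu^2
        bn_new[[key]]$mean <- bn_momentum * bn_new[[key]]$mean +
          (1 - bn_momentum) * mu
        bn_new[[key]]$var <- bn_momentum * bn_new[[key]]$var +
          (1 - bn_momentum) * v
      } else {
        mu <- model$bn[[key]]$mean
        v <- model$bn[[key]]$var
      }
      ivar <- 1 / sqrt(v + bn_eps)
      xhat <- add_bias(zk, -mu) * rep(ivar, each = B)
      bnout <- add_bias(xhat * rep(gamma, each = B), beta)
      a_new <- pmax(bnout, 0)
      if (keep_cache) {
        head_cache[[k]] <- list(a_in = a, z = zk, xhat = xhat, ivar = ivar,
                                bnout = bnout)
      }
      a <- a_new
    } else {
      if (keep_cache) head_cache[[k]] <- list(a_in = a, z = zk)
      logits <- zk
    }
  }
  probs <- softmax(logits)
  list(probs = probs, deep_feature = feat, logits = logits,
       cache = if (keep_cache) list(blocks = cache$blocks, head = head_cache,
                                    feat = feat, B = B) else NULL,
       bn = bn_new)
}

#' Model forward pass / prediction
#'
#' Runs the cascaded GRU blocks and classification head on one standardized
#' sample or a batch. Inference mode: batch normalization uses the stored
#' running statistics, so identical inputs always give identical predictions.
#'
#' @param model A `stress_model` from [init_model()] or [train_model()].
#' @param x An N x 7 standardized sample matrix (or `sample_matrix`), or a
#'   B x N x 7 array.
#' @return For a single sample: list with `probabilities` (4-vector, sums to
#'   1), `predicted_label` (argmax, 1..4) and `deep_feature`. For a batch:
#'   list with matrices `probabilities`, `predicted_label` vector and
#'   `deep_feature` matrix.
#' @export
model_forward <- function(model, x) {
  stopifnot(inherits(model, "stress_model"))
  if (inherits(x, "sample_matrix")) x <- x$values
  single <- length(dim(x)) == 2L
  if (single) x <- array(x, dim = c(1L, dim(x)))
  out <- forward_pass(model, x, training = FALSE)
  pred <- apply(out$probs, 1L, which.max)
  if (single) {
    list(probabilities = drop(out$probs), predicted_label = pred[1L],
         deep_feature = drop(out$deep_feature))
  } else {
    list(probabilities = out$probs, predicted_label = pred,
         deep_feature = out$deep_feature)
  }
}

#' Training loss: cross entropy plus L2 penalty
#'
#' `-(1/M) sum_i sum_k y_ik log(p_ik + 1e-12) + gamma * sum_W ||W||^2`, where
#' the L2 sum runs over all GRU and fully connected weight matrices (biases
#' and batch-norm parameters excluded).
#'
#' @param probs M x 4 matrix of predicted probabilities.
#' @param labels Integer labels 1..4 (length M).
#' @param params Flat parameter list (as in a `stress_model`); `NULL` for the
#'   pure cross-entropy term.
#' @param gamma L2 coefficient.
#' @return Scalar loss.
#' @export
model_loss <- function(probs, labels, params = NULL, gamma = 0) {
  M <- nrow(probs)
  stop_if(is.null(M) || M == 0L, "empty batch")
  stop_if(length(labels) != M, "labels must match the batch")
  ce <- -mean(log(probs[cbind(seq_len(M), labels)] + 1e-12))
  l2 <- 0
  if (!is.null(params) && gamma > 0) {
    for (nm in l2_param_names(params)) l2 <- l2 + sum(params[[nm]]^2)
  }
  ce + gamma * l2
}

#' Save / load a model checkpoint
#'
#' Serialized with the model configuration and batch-norm state embedded, so
#' a checkpoint restores to a ready-to-predict model.
#'
#' @param model A `stress_model`.
#' @param path File path (`.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "stress_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stop_if(!inherits(m, "stress_model"), "not a stress_model checkpoint: ", path)
  m
}
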