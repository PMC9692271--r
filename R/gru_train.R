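# Backpropagation through time, Adam, and the training loop.

# Batch-norm backward: given grad wrt the BN output, the cached normalized
# input xhat and 1/sqrt(var + eps), return grads wrt input, gamma, beta.
#' @noRd
bn_backward <- function(dout, xhat, ivar, gamma) {
  B <- nrow(dout)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(gamma, each = B)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- rep(ivar / B, each = B) *
    (B * dxhat - rep(s1, each = B) - xhat * rep(s2, each = B))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# One GRU cell backward step. `dh` is the total gradient at the cell output.
# Returns gradient wrt the step input, wrt the previous hidden state, and the
# per-parameter gradient contributions.
#' @noRd
cell_backward <- function(dh, X, Hprev, r, z, c_, cp) {
  dz <- dh * (Hprev - c_)
  dc <- dh * (1 - z)
  dh_prev <- dh * z

  dc_pre <- dc * (1 - c_^2)
  dRH <- dc_pre %*% t(cp$W_hc)
  dr <- dRH * Hprev
  dh_prev <- dh_prev + dRH * r
  dz_pre <- dz * z * (1 - z)
  dr_pre <- dr * r * (1 - r)
  dh_prev <- dh_prev + dz_pre %*% t(cp$W_hz) + dr_pre %*% t(cp$W_hr)
  dX <- dc_pre %*% t(cp$W_ic) + dz_pre %*% t(cp$W_iz) + dr_pre %*% t(cp$W_ir)

  grads <- list(
    W_ir = crossprod(X, dr_pre), W_hr = crossprod(Hprev, dr_pre),
    b_r = colSums(dr_pre),
    W_iz = crossprod(X, dz_pre), W_hz = crossprod(Hprev, dz_pre),
    b_z = colSums(dz_pre),
    W_ic = crossprod(X, dc_pre), W_hc = crossprod(r * Hprev, dc_pre),
    b_c = colSums(dc_pre)
  )
  list(dX = dX, dh_prev = dh_prev, grads = grads)
}

# Full backward pass. `fw` is the output of forward_pass(..., training = TRUE,
# keep_cache = TRUE); `labels` are integers 1..4. Returns a flat named list of
# gradients matching model$params (including the L2 term).
#' @noRd
backward_pass <- function(model, fw, labels, gamma) {
  cfg <- model$config
  p <- model$params
  B <- fw$cache$B
  N <- cfg$seq_len
  h <- cfg$hidden_units
  K <- cfg$layers_per_block
  n_head <- length(cfg$head_sizes)

  grads <- lapply(p, function(w) array(0, dim = dim(w) %||% length(w)))
  for (nm in names(grads)) {
    if (is.null(dim(p[[nm]]))) grads[[nm]] <- numeric(length(p[[nm]]))
  }

  Y <- matrix(0, B, 4L)
  Y[cbind(seq_len(B), labels)] <- 1
  da <- (fw$probs - Y) / B

  # head backward (output layer has no BN/ReLU)
  for (k in n_head:1) {
    hc <- fw$cache$head[[k]]
    W <- p[[sprintf("head%d.W", k)]]
    if (k < n_head) {
      dbnout <- da * (hc$bnout > 0)
      bb <- bn_backward(dbnout, hc$xhat, hc$ivar,
                        p[[sprintf("bn%d.gamma", k)]])
      grads[[sprintf("bn%d.gamma", k)]] <- bb$dgamma
      grads[[sprintf("bn%d.beta", k)]] <- bb$dbeta
      dz <- bb$dx
    } else {
      dz <- da
    }
    grads[[sprintf("head%d.W", k)]] <- crossprod(hc$a_in, dz)
    grads[[sprintf("head%d.b", k)]] <- colSums(dz)
    da <- dz %*% t(W)
  }

  # split the concatenated deep feature into per-block last-step gradients
  dlast <- lapply(seq_len(cfg$n_blocks), function(b) {
    da[, ((b - 1L) * h + 1L):(b * h), drop = FALSE]
  })

  # blocks in reverse; d_ext[[n]] = external grad on the block's top layer
  # output at step n (from the next block's inputs and/or the deep feature)
  zero <- matrix(0, B, h)
  d_from_next <- NULL
  for (b in cfg$n_blocks:1) {
    d_ext <- if (is.null(d_from_next)) {
      lapply(seq_len(N), function(n) zero)
    } else {
      d_from_next
    }
    d_ext[[N]] <- d_ext[[N]] + dlast[[b]]
    for (l in K:1) {
      lc <- fw$cache$blocks[[b]][[l]]
      cp <- cell_params_at(p, b, l)
      d_lower <- vector("list", N)
      dh_rec <- zero
      for (n in N:1) {
        dh <- d_ext[[n]] + dh_rec
        bk <- cell_backward(dh, lc$X[[n]], lc$Hprev[[n]], lc$r[[n]],
                            lc$z[[n]], lc$c[[n]], cp)
        dh_rec <- bk$dh_prev
        d_lower[[n]] <- bk$dX
        for (nm in names(bk$grads)) {
          key <- sprintf("g%d.%d.%s", b, l, nm)
          grads[[key]] <- grads[[key]] + bk$grads[[nm]]
        }
      }
      d_ext <- d_lower
    }
    d_from_next <- d_ext  # grads wrt the previous block's per-step outputs
  }

  if (gamma > 0) {
    for (nm in l2_param_names(p)) grads[[nm]] <- grads[[nm]] + 2 * gamma * p[[nm]]
  }
  grads
}

#' Training configuration
#'
#' Defaults are the full-scale training recipe: Adam with learning rate
#' 0.0002, batch size 52, 80 epochs, L2 coefficient 0.002, five repeated
#' experiments.
#'
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size (a short final batch is kept; the loss
#'   normalizes by the realized batch size).
#' @param epochs Number of training epochs (fixed; no early stopping).
#' @param l2_gamma L2 regularization coefficient.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param repeats Independent repeated experiments for averaging.
#' @param seed_base First seed; repeats use consecutive seeds.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 2e-4, batch_size = 52L, epochs = 80L,
                         l2_gamma = 0.002, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, repeats = 5L, seed_base = 1L) {
  stop_if(lr < 0, "lr must be >= 0")
  stop_if(!is_count(batch_size) || !is_count(epochs) || !is_count(repeats),
          "batch_size, epochs and repeats must be positive integers")
  stop_if(l2_gamma < 0, "l2_gamma must be >= 0")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), l2_gamma = l2_gamma,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 repeats = as.integer(repeats),
                 seed_base = as.integer(seed_base)),
            class = "train_config")
}

#' @noRd
batch_accuracy <- function(model, x, y) {
  if (!length(y)) return(NA_real_)
  pred <- model_forward(model, x)$predicted_label
  mean(pred == y)
}

#' Train a stress classification model
#'
#' Minimizes the cross-entropy + L2 loss with Adam over shuffled mini-batches
#' for a fixed number of epochs (no early stopping; the validation set is
#' monitored but never used for model selection). Deterministic given `seed`.
#'
#' @param model A `stress_model` from [init_model()].
#' @param x Training samples, M x N x 7 array (standardized).
#' @param y Integer labels 1..4, length M.
#' @param config A [train_config].
#' @param val_x,val_y Optional validation samples/labels (standardized with
#'   the *training* statistics), monitored once per epoch.
#' @param seed Integer seed controlling batch shuffling.
#' @param verbose Print one line per epoch.
#' @return The trained `stress_model` with element `history`, a data frame
#'   with columns `epoch`, `loss`, `train_acc`, `val_acc`.
#' @export
train_model <- function(model, x, y, config = train_config(),
                        val_x = NULL, val_y = NULL, seed = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(model, "stress_model"), inherits(config, "train_config"))
  M <- dim(x)[1]
  stop_if(is.na(M) || M < 1L, "empty training set")
  stop_if(length(y) != M, "labels must match the samples")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))

  adam_m <- lapply(model$params, function(w) w * 0)
  adam_v <- lapply(model$params, function(w) w * 0)
  t_step <- 0L
  hist <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(M)
    starts <- seq(1L, M, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, M)]
      xb <- x[idx, , , drop = FALSE]
      yb <- y[idx]
      fw <- forward_pass(model, xb, training = TRUE, keep_cache = TRUE)
      model$bn <- fw$bn
      ep_loss <- ep_loss + model_loss(fw$probs, yb, model$params,
                                      config$l2_gamma) * length(idx)
      g <- backward_pass(model, fw, yb, config$l2_gamma)
      t_step <- t_step + 1L
      bc1 <- 1 - config$beta1^t_step
      bc2 <- 1 - config$beta2^t_step
      for (nm in names(model$params)) {
        adam_m[[nm]] <- config$beta1 * adam_m[[nm]] + (1 - config$beta1) * g[[nm]]
        adam_v[[nm]] <- config$beta2 * adam_v[[nm]] + (1 - config$beta2) * g[[nm]]^2
        model$params[[nm]] <- model$params[[nm]] -
          config$lr * (adam_m[[nm]] / bc1) / (sqrt(adam_v[[nm]] / bc2) + config$eps)
      }
    }
    # re-estimate the batch-norm statistics over the full training set
    # ("precise BN"): the exponential average can lag the activations badly
    # in small-data regimes, making inference inconsistent with training
    model$bn <- forward_pass(model, x, training = TRUE, bn_momentum = 0)$bn
    tr_acc <- batch_accuracy(model, x, y)
    va_acc <- if (is.null(val_x)) NA_real_ else batch_accuracy(model, val_x, val_y)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / M,
                                train_acc = tr_acc, val_acc = va_acc)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  train %.3f  val %s", epoch,
                      ep_loss / M, tr_acc,
                      if (is.na(va_acc)) "-" else sprintf("%.3f", va_acc)))
    }
  }
  model$history <- do.call(rbind, hist)
  model
}
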