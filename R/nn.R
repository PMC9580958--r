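# Minimal per-protein convolutional regression machinery.
#
# Both iterative models are two convolutional layers along the sequence axis
# with a Tanh between them; the feed-forward ANN is the kernel-length-1
# special case. Batches are single proteins (variable length, no padding
# artifacts); optimization is Adam with the amsgrad correction and L2 weight
# decay added to the gradient, matching the usual deep-learning toolkit
# semantics.

# Zero-pad a L x C matrix to (L + k - 1) x C with (k-1)/2 rows each side (k odd).
pad_rows <- function(X, k) {
  if (k == 1L) return(X)
  h <- (k - 1L) %/% 2L
  C <- ncol(X)
  rbind(matrix(0, h, C), X, matrix(0, h, C))
}

# im2col: row i of the result is the flattened k-residue window centered at i,
# grouped tap-major (tap 1 columns, then tap 2 columns, ...).
unfold_rows <- function(X, k) {
  L <- nrow(X)
  if (k == 1L) return(X)
  Xp <- pad_rows(X, k)
  do.call(cbind, lapply(seq_len(k), function(j) Xp[j:(j + L - 1L), , drop = FALSE]))
}

# Scatter-add the gradient w.r.t. a conv layer's input.
# dY: L x C_out, W: (k*C_in) x C_out -> L x C_in
fold_back_rows <- function(dY, W, k, C_in) {
  L <- nrow(dY)
  if (k == 1L) return(dY %*% t(W))
  h <- (k - 1L) %/% 2L
  dXp <- matrix(0, L + k - 1L, C_in)
  for (j in seq_len(k)) {
    Wj <- W[((j - 1L) * C_in + 1L):(j * C_in), , drop = FALSE]
    dXp[j:(j + L - 1L), ] <- dXp[j:(j + L - 1L), ] + dY %*% t(Wj)
  }
  dXp[(h + 1L):(h + L), , drop = FALSE]
}

nn_init <- function(dim, kernel_len, channels) {
  # uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)) per layer
  r1 <- 1 / sqrt(kernel_len * dim)
  r2 <- 1 / sqrt(kernel_len * channels)
  list(
    W1 = matrix(stats::runif(kernel_len * dim * channels, -r1, r1),
                kernel_len * dim, channels),
    b1 = stats::runif(channels, -r1, r1),
    W2 = matrix(stats::runif(kernel_len * channels, -r2, r2),
                kernel_len * channels, 1L),
    b2 = stats::runif(1L, -r2, r2)
  )
}

nn_forward <- function(params, X, k, keep = FALSE) {
  U1 <- unfold_rows(X, k)
  H <- tanh(sweep(U1 %*% params$W1, 2L, params$b1, "+"))
  U2 <- unfold_rows(H, k)
  y <- as.numeric(U2 %*% params$W2 + params$b2)
  if (keep) list(y = y, U1 = U1, H = H, U2 = U2) else y
}

# Mean-squared-error gradient for one protein.
nn_backward <- function(params, fwd, y_true, k, dim, channels) {
  L <- length(y_true)
  dY <- matrix(2 * (fwd$y - y_true) / L, ncol = 1L)
  dW2 <- t(fwd$U2) %*% dY
  db2 <- sum(dY)
  dH <- fold_back_rows(dY, params$W2, k, channels)
  dA <- dH * (1 - fwd$H^2)
  dW1 <- t(fwd$U1) %*% dA
  db1 <- colSums(dA)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_state <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, vhat_max = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay, amsgrad,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    vv <- if (amsgrad) {
      state$vhat_max[[nm]] <- pmax(state$vhat_max[[nm]], state$v[[nm]])
      state$vhat_max[[nm]]
    } else state$v[[nm]]
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(vv / bc2) + eps)
  }
  list(params = params, state = state)
}

# Full training loop: per-protein batches, shuffled epochs, early stopping on
# validation loss with best-state restoration (earliest best kept on ties).
# xs/ys: lists of matrices/score vectors. All randomness comes from the
# caller's RNG stream.
nn_train <- function(xs, ys, k, dim, channels,
                     lr, weight_decay, amsgrad,
                     val_fraction, patience, max_epochs) {
  n <- length(xs)
  n_val <- max(1L, round(val_fraction * n))
  if (n_val >= n) stop("too few proteins for a train/validation split")
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)

  params <- nn_init(dim, k, channels)
  state <- adam_state(params)
  val_loss <- function(p) {
    sse <- 0; m <- 0
    for (i in val_idx) {
      yhat <- nn_forward(p, xs[[i]], k)
      sse <- sse + sum((yhat - ys[[i]])^2)
      m <- m + length(yhat)
    }
    sse / m
  }
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    tr_sse <- 0; tr_m <- 0
    for (i in sample(tr_idx)) {
      fwd <- nn_forward(params, xs[[i]], k, keep = TRUE)
      tr_sse <- tr_sse + sum((fwd$y - ys[[i]])^2)
      tr_m <- tr_m + length(fwd$y)
      grads <- nn_backward(params, fwd, ys[[i]], k, dim, channels)
      upd <- adam_step(params, grads, state, lr, weight_decay, amsgrad)
      params <- upd$params
      state <- upd$state
    }
    vl <- val_loss(params)
    if (!is.finite(vl) || !is.finite(tr_sse)) {
      stop(sprintf("non-finite loss at epoch %d", epoch))
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tr_sse / tr_m,
                                         val_loss = vl))
    if (vl < best$loss) {          # strict: ties keep the earliest epoch
      best <- list(loss = vl, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(params = best$params, history = history, best_epoch = best$epoch,
       best_val_loss = best$loss, val_idx = val_idx)
}
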