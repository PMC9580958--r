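#' Specify a disorder prediction model
#'
#' Five shallow heads over per-residue embeddings are supported:
#' \describe{
#'   \item{`linreg`}{ordinary least squares on all N dimensions (closed form).}
#'   \item{`linreg1d`}{least squares on the single most disorder-informative
#'     dimension (default index 295 for 1024-dimensional inputs).}
#'   \item{`logreg`}{ridge logistic regression predicting the probability of
#'     order (score > 8).}
#'   \item{`ann`}{per-residue two-layer feed-forward network (Tanh hidden
#'     layer, default 32 units).}
#'   \item{`cnn`}{two convolutional layers along the sequence (kernel length
#'     5 in both layers, 28 channels, Tanh between), zero-padded so every
#'     residue receives exactly one output.}
#' }
#' The iterative models train with Adam (learning rate 0.001, amsgrad,
#' weight decay 0.001), one protein per optimizer step.
#'
#' @param kind one of `"linreg"`, `"linreg1d"`, `"logreg"`, `"ann"`, `"cnn"`.
#' @param dim embedding dimension N the model expects.
#' @param linreg1d_index 1-based informative dimension for `linreg1d`.
#' @param kernel_len odd convolution kernel length (cnn only), default 5.
#' @param channels first-layer output channels (cnn only), default 28.
#' @param hidden_units hidden layer width (ann only), default 32.
#' @param lr Adam learning rate, default 0.001.
#' @param weight_decay L2 weight decay added to the gradient, default 0.001.
#' @param amsgrad use the amsgrad second-moment correction, default `TRUE`.
#' @param logreg_lambda ridge penalty for `logreg` on the glmnet scale,
#'   default `NULL` = `1/n_residues` (an L2 "strength 1" convention).
#' @param seed integer seed controlling the train/validation split, weight
#'   initialization and epoch shuffling, default 42.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("linreg", "linreg1d", "logreg", "ann", "cnn"),
                       dim,
                       linreg1d_index = 295L,
                       kernel_len = 5L,
                       channels = 28L,
                       hidden_units = 32L,
                       lr = 0.001,
                       weight_decay = 0.001,
                       amsgrad = TRUE,
                       logreg_lambda = NULL,
                       seed = 42L) {
  kind <- match.arg(kind)
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  kernel_len <- as.integer(kernel_len)
  if (kernel_len < 1L || kernel_len %% 2L == 0L) {
    stop("kernel_len must be odd so each residue receives one output")
  }
  if (kind == "linreg1d" && (linreg1d_index < 1L || linreg1d_index > dim)) {
    stop("linreg1d_index out of range for this embedding dimension")
  }
  structure(list(kind = kind, dim = dim,
                 linreg1d_index = as.integer(linreg1d_index),
                 kernel_len = kernel_len, channels = as.integer(channels),
                 hidden_units = as.integer(hidden_units),
                 lr = lr, weight_decay = weight_decay, amsgrad = amsgrad,
                 logreg_lambda = logreg_lambda,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Training protocol for the iterative models
#'
#' Proteins are split 90/10 into training and validation sets; training stops
#' after `patience` epochs without validation-loss improvement and the
#' best-validation parameter state is restored.
#'
#' @param val_fraction fraction of proteins held out for validation,
#'   default 0.10.
#' @param patience epochs without improvement before stopping, default 10.
#' @param max_epochs hard epoch cap, default 200.
#' @return A list of class `train_config`.
#' @export
train_config <- function(val_fraction = 0.10, patience = 10L,
                         max_epochs = 200L) {
  stopifnot(val_fraction > 0, val_fraction < 1, patience >= 1L,
            max_epochs >= 1L)
  structure(list(val_fraction = val_fraction, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs)),
            class = "train_config")
}

# Pair records with embeddings, dropping residues without valid scores.
# Returns lists xs (matrices) / ys (score vectors), one entry per protein.
assemble_training_data <- function(spec, records, embeddings) {
  if (length(records) == 0L) stop("empty training set")
  xs <- list(); ys <- list()
  for (rec in records) {
    E <- embeddings[[rec$id]]
    if (is.null(E)) stop(sprintf("no embedding for protein '%s'", rec$id))
    if (ncol(E) != spec$dim) {
      stop(sprintf("embedding dim %d for '%s' != model dim %d",
                   ncol(E), rec$id, spec$dim))
    }
    if (nrow(E) != length(rec$scores)) {
      stop(sprintf("embedding rows %d for '%s' != %d residues",
                   nrow(E), rec$id, length(rec$scores)))
    }
    keep <- rec$valid_mask
    if (!any(keep)) next
    xs[[length(xs) + 1L]] <- unclass(E)[keep, , drop = FALSE]
    ys[[length(ys) + 1L]] <- rec$scores[keep]
  }
  if (length(xs) == 0L) stop("no residues with valid scores in training set")
  list(xs = xs, ys = ys)
}

#' Fit a disorder prediction model
#'
#' Linear heads are fit by ordinary least squares with intercept (closed
#' form); the logistic head by ridge-penalized maximum likelihood; the ANN
#' and CNN by Adam with per-protein batches and early stopping on a 90/10
#' protein-level validation split. All randomness (split, initialization,
#' epoch shuffling) derives from `spec$seed`. Residues without valid CheZOD
#' scores are dropped before presentation.
#'
#' @param spec a [model_spec()].
#' @param records list of [protein_record()]s with ground-truth scores.
#' @param embeddings named list of [embedding_matrix()] (names = protein ids).
#' @param train a [train_config()] (iterative models only).
#' @return A fitted model of class `chezod_model` carrying `spec`, parameter
#'   arrays and, for iterative models, the per-epoch training history.
#' @export
fit_disorder_model <- function(spec, records, embeddings,
                               train = train_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(train, "train_config"))
  dat <- assemble_training_data(spec, records, embeddings)
  set.seed(spec$seed)
  fitted <- switch(
    spec$kind,
    linreg = fit_ols(do.call(rbind, dat$xs), unlist(dat$ys)),
    linreg1d = {
      X <- do.call(rbind, dat$xs)[, spec$linreg1d_index, drop = FALSE]
      fit_ols(X, unlist(dat$ys))
    },
    logreg = fit_ridge_logreg(do.call(rbind, dat$xs), unlist(dat$ys), spec),
    ann = nn_train(dat$xs, dat$ys, k = 1L, dim = spec$dim,
                   channels = spec$hidden_units,
                   lr = spec$lr, weight_decay = spec$weight_decay,
                   amsgrad = spec$amsgrad,
                   val_fraction = train$val_fraction,
                   patience = train$patience, max_epochs = train$max_epochs),
    cnn = nn_train(dat$xs, dat$ys, k = spec$kernel_len, dim = spec$dim,
                   channels = spec$channels,
                   lr = spec$lr, weight_decay = spec$weight_decay,
                   amsgrad = spec$amsgrad,
                   val_fraction = train$val_fraction,
                   patience = train$patience, max_epochs = train$max_epochs)
  )
  structure(list(spec = spec,
                 params = fitted$params,
                 history = fitted$history,
                 best_epoch = fitted$best_epoch,
                 best_val_loss = fitted$best_val_loss),
            class = "chezod_model")
}

fit_ols <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, X), y)
  co <- fit$coefficients
  co[is.na(co)] <- 0            # rank-deficient columns contribute nothing
  list(params = list(coef = unname(co)), history = NULL,
       best_epoch = NULL, best_val_loss = NULL)
}

fit_ridge_logreg <- function(X, y, spec) {
  lab <- as.integer(y > CHEZOD_DISORDER_THRESHOLD)   # 1 = order
  if (length(unique(lab)) < 2L) {
    stop("logreg requires both order and disorder residues in training data")
  }
  lambda <- if (is.null(spec$logreg_lambda)) 1 / length(lab) else spec$logreg_lambda
  fit <- glmnet::glmnet(X, lab, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  co <- as.numeric(stats::coef(fit))
  list(params = list(coef = co), history = NULL,
       best_epoch = NULL, best_val_loss = NULL)
}

#' Predict per-residue disorder from an embedding matrix
#'
#' Returns exactly one value per input residue: a continuous predicted
#' CheZOD score for the regression heads, or an order probability in
#' \[0, 1\] for the logistic head. The convolutional layers use zero padding
#' of `(kernel_len - 1) / 2` on each side, so sequences shorter than the
#' kernel still yield one output per residue.
#'
#' @param object a fitted `chezod_model`.
#' @param embedding an [embedding_matrix()] (or plain L x N matrix) with N
#'   matching the model's `dim`.
#' @param ... unused.
#' @return Numeric vector of length `nrow(embedding)`.
#' @export
predict.chezod_model <- function(object, embedding, ...) {
  X <- unclass(as.matrix(embedding))
  if (ncol(X) != object$spec$dim) {
    stop(sprintf("embedding dim %d != model dim %d", ncol(X), object$spec$dim))
  }
  switch(
    object$spec$kind,
    linreg = as.numeric(cbind(1, X) %*% object$params$coef),
    linreg1d = as.numeric(
      cbind(1, X[, object$spec$linreg1d_index, drop = FALSE]) %*%
        object$params$coef),
    logreg = as.numeric(stats::plogis(cbind(1, X) %*% object$params$coef)),
    ann = nn_forward(object$params, X, k = 1L),
    cnn = nn_forward(object$params, X, k = object$spec$kernel_len)
  )
}

#' @export
print.chezod_model <- function(x, ...) {
  cat(sprintf("<chezod_model> kind=%s dim=%d parameters=%d\n",
              x$spec$kind, x$spec$dim, n_parameters(x)))
  if (!is.null(x$best_epoch)) {
    cat(sprintf("  best epoch %d, validation MSE %.5g\n",
                x$best_epoch, x$best_val_loss))
  }
  invisible(x)
}

#' Total number of free parameters of a fitted model
#'
#' For the default convolutional head on 1024-dimensional embeddings this is
#' `1024*5*28 + 28 + 28*5*1 + 1`.
#'
#' @param model a fitted `chezod_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}
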