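MODEL_FORMAT <- "chezod-model"
MODEL_FORMAT_VERSION <- 1L

#' Save a fitted model to a portable text checkpoint
#'
#' The checkpoint is a single text file: line 1 is a JSON header recording
#' the format version, the full model spec, the seed, the training history
#' and the name/dimensions of every parameter array; each following line
#' holds one array's values, column-major, serialized with 17 significant
#' digits so that a save/load round trip reproduces predictions
#' bit-identically.
#'
#' @param model a fitted `chezod_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "chezod_model"))
  arrays <- lapply(model$params, function(p) {
    list(dims = if (is.matrix(p)) dim(p) else length(p))
  })
  header <- list(
    format = MODEL_FORMAT,
    version = MODEL_FORMAT_VERSION,
    spec = model$spec[!vapply(model$spec, is.null, TRUE)],
    best_epoch = model$best_epoch,
    best_val_loss = model$best_val_loss,
    history = model$history,
    arrays = lapply(names(model$params), function(nm) {
      c(list(name = nm), arrays[[nm]])
    })
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
  for (p in model$params) {
    writeLines(paste(sprintf("%.17g", as.numeric(p)), collapse = " "), con)
  }
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path checkpoint path.
#' @return A fitted `chezod_model`. Truncated files and unknown format
#'   versions raise errors.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop(sprintf("empty model file: %s", path))
  header <- tryCatch(jsonlite::fromJSON(lines[1L], simplifyVector = TRUE),
                     error = function(e) stop(sprintf(
                       "not a model checkpoint: %s (%s)", path, conditionMessage(e))))
  if (!identical(header$format, MODEL_FORMAT)) {
    stop(sprintf("not a %s file: %s", MODEL_FORMAT, path))
  }
  if (!identical(as.integer(header$version), MODEL_FORMAT_VERSION)) {
    stop(sprintf("unsupported model format version %s (expected %d)",
                 header$version, MODEL_FORMAT_VERSION))
  }
  n_arr <- nrow(header$arrays)
  if (length(lines) < 1L + n_arr) {
    stop(sprintf("truncated model file: %s (%d of %d arrays present)",
                 path, length(lines) - 1L, n_arr))
  }
  params <- list()
  for (i in seq_len(n_arr)) {
    nm <- header$arrays$name[i]
    dims <- header$arrays$dims[[i]]
    vals <- as.numeric(strsplit(trimws(lines[1L + i]), " ", fixed = TRUE)[[1L]])
    if (length(vals) != prod(dims)) {
      stop(sprintf("truncated model file: array '%s' has %d of %d values",
                   nm, length(vals), prod(dims)))
    }
    params[[nm]] <- if (length(dims) == 2L) matrix(vals, dims[1L], dims[2L]) else vals
  }
  sp <- header$spec
  spec <- model_spec(kind = sp$kind, dim = sp$dim,
                     linreg1d_index = sp$linreg1d_index,
                     kernel_len = sp$kernel_len, channels = sp$channels,
                     hidden_units = sp$hidden_units, lr = sp$lr,
                     weight_decay = sp$weight_decay, amsgrad = sp$amsgrad,
                     logreg_lambda = sp$logreg_lambda, seed = sp$seed)
  structure(list(spec = spec, params = params,
                 history = header$history,
                 best_epoch = header$best_epoch,
                 best_val_loss = header$best_val_loss),
            class = "chezod_model")
}
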