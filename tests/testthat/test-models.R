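test_that("linear heads recover an exact planted relation", {
  d <- tiny_dataset(n = 30, noise_sd = 0, aa_scale = 0)
  train <- d$records[1:24]; test <- d$records[25:30]
  m <- fit_disorder_model(model_spec("linreg", dim = 16), train, d$embeddings)
  expect_gte(heldout_rho(m, test, d$embeddings), 0.999)
  m1 <- fit_disorder_model(model_spec("linreg1d", dim = 16, linreg1d_index = 3),
                           train, d$embeddings)
  expect_gte(heldout_rho(m1, test, d$embeddings), 0.999)
  # prediction is exactly w.e + b
  co <- m$params$coef
  E <- d$embeddings[[test[[1]]$id]]
  expect_equal(predict(m, E), as.numeric(cbind(1, unclass(E)) %*% co),
               tolerance = 0)
})

test_that("closed-form fits are bit-stable across repeated runs", {
  d <- tiny_dataset(n = 20)
  m1 <- fit_disorder_model(model_spec("linreg", dim = 16), d$records, d$embeddings)
  m2 <- fit_disorder_model(model_spec("linreg", dim = 16), d$records, d$embeddings)
  expect_identical(m1$params, m2$params)
})

test_that("residues without valid scores are dropped before fitting", {
  d <- tiny_dataset(n = 20, noise_sd = 0, aa_scale = 0)
  # poison some scores with sentinels; fit must be unaffected by those rows
  rec <- d$records[[1]]
  s <- rec$scores
  s[1:5] <- 900
  d$records[[1]] <- protein_record(rec$id, rec$sequence, s)
  m <- fit_disorder_model(model_spec("linreg", dim = 16), d$records, d$embeddings)
  expect_gte(heldout_rho(m, d$records[2:20], d$embeddings), 0.999)
})

test_that("fit contracts: empty sets and dimension mismatches error", {
  d <- tiny_dataset(n = 10)
  expect_error(fit_disorder_model(model_spec("linreg", dim = 16), list(),
                                  d$embeddings), "empty training set")
  expect_error(fit_disorder_model(model_spec("linreg", dim = 32), d$records,
                                  d$embeddings), "dim 16 .* != model dim 32")
  m <- fit_disorder_model(model_spec("linreg", dim = 16), d$records, d$embeddings)
  expect_error(predict(m, matrix(0, 3, 8)), "dim 8 != model dim 16")
  expect_error(model_spec("cnn", dim = 16, kernel_len = 4), "odd")
})

test_that("logreg outputs order probabilities that separate the classes", {
  d <- tiny_dataset(n = 60, noise_sd = 0.3, aa_scale = 0.3)
  train <- d$records[1:48]; test <- d$records[49:60]
  m <- fit_disorder_model(model_spec("logreg", dim = 16), train, d$embeddings)
  p <- unlist(lapply(test, function(r) predict(m, d$embeddings[[r$id]])))
  expect_true(all(p >= 0 & p <= 1))
  truth <- unlist(lapply(test, `[[`, "scores"))
  expect_gt(auc(p, truth > 8), 0.9)
})

test_that("the CNN has the stated architecture and one output per residue", {
  d <- tiny_dataset(n = 30)
  m <- fit_disorder_model(model_spec("cnn", dim = 16, seed = 42),
                          d$records, d$embeddings,
                          train_config(max_epochs = 3))
  expect_equal(n_parameters(m), 16 * 5 * 28 + 28 + 28 * 5 * 1 + 1)
  for (L in c(1L, 4L, 7L, 1000L)) {
    expect_length(predict(m, matrix(0, L, 16)), L)
  }
})

test_that("iterative training is seed-deterministic", {
  d <- tiny_dataset(n = 25)
  tc <- train_config(max_epochs = 4)
  for (kind in c("ann", "cnn")) {
    m1 <- fit_disorder_model(model_spec(kind, dim = 16, seed = 42),
                             d$records, d$embeddings, tc)
    m2 <- fit_disorder_model(model_spec(kind, dim = 16, seed = 42),
                             d$records, d$embeddings, tc)
    expect_identical(m1$params, m2$params)
    expect_identical(m1$history, m2$history)
  }
})

test_that("early stopping restores the best-validation state", {
  d <- tiny_dataset(n = 40, noise_sd = 1.5)
  tc <- train_config(patience = 3, max_epochs = 60)
  m <- fit_disorder_model(model_spec("ann", dim = 16, hidden_units = 8),
                          d$records, d$embeddings, tc)
  h <- m$history
  expect_equal(m$best_val_loss, min(h$val_loss))
  expect_equal(m$best_epoch, which.min(h$val_loss))  # earliest best on ties
  if (nrow(h) < tc$max_epochs) {
    tail_losses <- h$val_loss[(m$best_epoch + 1):nrow(h)]
    expect_length(tail_losses, tc$patience)
    expect_true(all(tail_losses >= m$best_val_loss))
  }
})

test_that("linreg coefficients align with the planted direction, degrading with noise", {
  cosines <- vapply(c(0, 0.5, 2), function(ns) {
    vals <- vapply(1:5, function(seed) {
      d <- tiny_dataset(n = 40, noise_sd = ns, aa_scale = 0, seed = seed)
      m <- fit_disorder_model(model_spec("linreg", dim = 16), d$records,
                              d$embeddings)
      w <- m$params$coef[-1]
      abs(w[3]) / sqrt(sum(w^2))
    }, 0.0)
    mean(vals)
  }, 0.0)
  expect_gte(cosines[1], 0.99)
  expect_true(all(diff(cosines) < 0))
})

test_that("model checkpoints round-trip predictions bit-identically", {
  d <- tiny_dataset(n = 25)
  f <- withr::local_tempfile(fileext = ".txt")
  for (kind in c("linreg", "linreg1d", "logreg", "cnn")) {
    spec <- model_spec(kind, dim = 16, linreg1d_index = 3)
    m <- fit_disorder_model(spec, d$records, d$embeddings,
                            train_config(max_epochs = 2))
    save_model(m, f)
    m2 <- load_model(f)
    E <- d$embeddings[[1]]
    expect_identical(predict(m, E), predict(m2, E))
    expect_equal(m2$spec$kind, kind)
  }
})

test_that("loading rejects truncated and alien files, and dim mismatches surface", {
  d <- tiny_dataset(n = 20)
  m <- fit_disorder_model(model_spec("linreg", dim = 16), d$records, d$embeddings)
  f <- withr::local_tempfile(fileext = ".txt")
  save_model(m, f)
  lines <- readLines(f)
  writeLines(lines[1], f)
  expect_error(load_model(f), "truncated")
  writeLines("not json at all", f)
  expect_error(load_model(f), "not a")
  save_model(m, f)
  m2 <- load_model(f)
  expect_error(predict(m2, matrix(0, 2, 1024)), "!= model dim 16")
})
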