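test_that("spearman_rho matches hand-checkable cases and flags degeneracy", {
  expect_equal(spearman_rho(1:3, 1:3), 1.0)
  expect_equal(spearman_rho(1:3, 3:1), -1.0)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman_rho(1, 1), "at least 2")
})

test_that("spearman_rho is invariant under strictly increasing transforms", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    r <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y^3 + 2 * y), r, tolerance = 1e-12)
  }
})

test_that("auc handles separation, ties and orientation flips", {
  expect_equal(auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_true(is.na(auc(1:4, rep(TRUE, 4))))
  set.seed(31)
  p <- rnorm(60); lab <- rep(c(TRUE, FALSE), 30)
  expect_equal(auc(-p, lab), 1 - auc(p, lab), tolerance = 1e-12)  # no ties
  expect_equal(auc(exp(p), lab), auc(p, lab), tolerance = 1e-12)
  # cross-check against an established ROC implementation
  ref <- as.numeric(pROC::auc(pROC::roc(lab, p, quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(auc(p, lab), ref, tolerance = 1e-12)
})

test_that("strict and ties-as-half AUC differ by exactly the tied-pair term", {
  set.seed(41)
  for (i in 1:30) {
    p <- sample(1:6, 40, replace = TRUE)  # heavy ties
    lab <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.6, 0.4))
    if (!any(lab) || all(lab)) next
    half <- oracle_auc(p, lab, "half")
    strict <- oracle_auc(p, lab, "strict")
    expect_equal(auc(p, lab, "half"), half, tolerance = 1e-12)
    expect_equal(auc(p, lab, "strict"), strict, tolerance = 1e-12)
    n_tied <- sum(outer(p[lab], p[!lab], "=="))
    expect_equal(half - strict, n_tied / (2 * sum(lab) * sum(!lab)),
                 tolerance = 1e-12)
  }
})

test_that("roc_curve is a staircase whose trapezoid area equals the AUC", {
  set.seed(51)
  for (i in 1:20) {
    p <- c(rnorm(30), sample(1:3, 10, replace = TRUE))
    lab <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (!any(lab) || all(lab)) next
    roc <- roc_curve(p, lab)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(roc_auc(roc), auc(p, lab), tolerance = 1e-12)
  }
  # perfect separation passes through (0, 1); all-ties is the diagonal
  roc <- roc_curve(c(2, 2, 1, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  roc2 <- roc_curve(rep(1, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(roc2), 2L)
  expect_equal(roc_auc(roc2), 0.5)
})

test_that("bootstrap is seeded, drops degenerate sets, and has zero CI for constants", {
  x <- rnorm(100); y <- rnorm(100)
  b1 <- bootstrap_stat(spearman_rho, x, y, n_sets = 50, seed = 7)
  b2 <- bootstrap_stat(spearman_rho, x, y, n_sets = 50, seed = 7)
  expect_identical(b1$per_set_stats, b2$per_set_stats)
  const <- bootstrap_stat(function(t, p) 0.5, x, y, n_sets = 50, seed = 1)
  expect_equal(const$mean_stat, 0.5)
  expect_equal(const$ci95_halfwidth, 0)
  nacount <- bootstrap_stat(function(t, p) if (mean(t) > 0) 1 else NA_real_,
                            x, y, n_sets = 50, seed = 1)
  expect_equal(length(nacount$per_set_stats) + nacount$n_dropped, 50L)
  expect_error(bootstrap_stat(function(t, p) NA_real_, x, y, n_sets = 10,
                              seed = 1), "undefined on every")
})

test_that("bootstrap mean approaches the plug-in statistic for large n_sets", {
  set.seed(61)
  x <- rnorm(300); y <- x + rnorm(300)
  plug <- spearman_rho(x, y)
  b <- bootstrap_stat(spearman_rho, x, y, n_sets = 10000, seed = 2)
  se_of_mean <- b$sd / sqrt(length(b$per_set_stats))
  expect_lt(abs(b$mean_stat - plug), max(3 * se_of_mean, 0.01))
})

test_that("evaluate_predictions pools residues and honors orientation", {
  d <- tiny_dataset(n = 15, noise_sd = 0, aa_scale = 0)
  preds <- lapply(d$records, function(r) r$scores)
  names(preds) <- vapply(d$records, `[[`, "", "id")
  ev <- evaluate_predictions(d$records, preds, n_boot = 50, seed = 1)
  expect_equal(ev$rho, 1)
  expect_equal(ev$auc, 1)
  neg <- lapply(preds, function(p) -p)
  ev2 <- evaluate_predictions(d$records, neg, n_boot = 50, seed = 1,
                              higher_is_disorder = TRUE)
  expect_equal(ev2$rho, 1)
  bad <- preds; bad[[1]] <- bad[[1]][-1]
  expect_error(evaluate_predictions(d$records, bad, n_boot = 10),
               "length-mismatched .*SYN0001")
})

test_that("per-class evaluation reports the three region strata", {
  d <- generate_dataset(synthetic_config(n_proteins = 40, dim = 4,
                                         informative_dim_index = 1,
                                         order_fraction_target = 0.5,
                                         region_smoothing = 25, seed = 12))
  preds <- lapply(d$records, function(r) r$scores + rnorm(length(r$scores), 0, 2))
  names(preds) <- vapply(d$records, `[[`, "", "id")
  ev <- evaluate_predictions(d$records, preds, n_boot = 30, seed = 1,
                             per_class = TRUE)
  expect_named(ev$per_class, c("ORDERED", "SHORT_DISORDER", "LONG_DISORDER"))
  pc_n <- sum(vapply(ev$per_class, function(x) if (is.null(x)) 0L else x$n, 0L))
  expect_equal(pc_n, ev$n_residues)
})
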