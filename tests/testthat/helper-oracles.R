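# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately take the slow, obvious route.

# Spearman via base R's correlation (independent of the package's
# rank-arithmetic implementation).
oracle_spearman <- function(truth, pred) {
  suppressWarnings(stats::cor(truth, pred, method = "spearman"))
}

# AUC by the exhaustive double loop over all (positive, negative) pairs.
oracle_auc <- function(pred, is_positive, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  pos <- pred[is_positive]
  neg <- pred[!is_positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (yp in pos) {
    for (yn in neg) {
      total <- total + (yp > yn) + if (ties == "half") 0.5 * (yp == yn) else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Three-class region taxonomy by explicit enumeration of maximal runs.
oracle_classify <- function(scores, theta = 8, lmin = 30L) {
  n <- length(scores)
  lab <- rep("ORDERED", n)
  i <- 1L
  while (i <= n) {
    if (scores[i] <= theta) {
      j <- i
      while (j < n && scores[j + 1L] <= theta) j <- j + 1L
      lab[i:j] <- if (j - i + 1L >= lmin) "LONG_DISORDER" else "SHORT_DISORDER"
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  lab
}

# Shrunken-window sliding mean, one position at a time.
oracle_smooth <- function(values, window) {
  h <- (window - 1L) %/% 2L
  vapply(seq_along(values), function(i) {
    mean(values[max(1L, i - h):min(length(values), i + h)])
  }, 0.0)
}

# Pre-filter counts by direct enumeration of the four cells.
oracle_prefilter <- function(mean_pred, mean_plddt, t, cutoff = 70) {
  P <- 0; FN <- 0; TN <- 0; TP <- 0
  for (id in names(mean_pred)) {
    wanted <- mean_plddt[[id]] >= cutoff
    filtered <- mean_pred[[id]] < t
    P <- P + wanted
    FN <- FN + (filtered && wanted)
    TN <- TN + (filtered && !wanted)
    TP <- TP + (!filtered && wanted)
  }
  n <- length(mean_pred)
  list(cost = if (P > 0) FN / P else NA_real_,
       gain = (FN + TN) / n,
       accuracy = (TP + TN) / n)
}

# Small synthetic dataset shorthand for model tests.
tiny_dataset <- function(n = 40L, dim = 16L, idx = 3L, noise_sd = 0.5,
                         aa_scale = 0.5, seed = 7L, ...) {
  generate_dataset(synthetic_config(
    n_proteins = n, dim = dim, informative_dim_index = idx,
    noise_sd = noise_sd, aa_cluster_scale = aa_scale, seed = seed, ...))
}

# Fit on train records, return held-out pooled Spearman on test records.
heldout_rho <- function(model, test_records, embeddings) {
  truth <- numeric(0); pred <- numeric(0)
  for (rec in test_records) {
    keep <- rec$valid_mask
    truth <- c(truth, rec$scores[keep])
    pred <- c(pred, predict(model, embeddings[[rec$id]])[keep])
  }
  spearman_rho(truth, pred)
}
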