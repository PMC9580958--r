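#' Spearman rank correlation between truth and prediction
#'
#' Computed from first principles as the Pearson correlation of the two
#' average-rank vectors: with `u_i`, `v_i` the ranks of the i-th truth and
#' predicted values,
#' `rho = sum((u - mean(u)) * (v - mean(v))) / sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))`.
#'
#' @param truth numeric vector of ground-truth scores.
#' @param pred numeric vector of predictions, same length, `m >= 2`.
#' @return The correlation in \[-1, 1\], or `NA_real_` when either vector is
#'   constant (undefined, never silently 0).
#' @export
spearman_rho <- function(truth, pred) {
  m <- length(truth)
  if (m != length(pred)) stop("truth and pred must have equal length")
  if (m < 2L) stop("need at least 2 paired values")
  if (anyNA(truth) || anyNA(pred)) stop("NA values not allowed")
  u <- rank(truth, ties.method = "average")
  v <- rank(pred, ties.method = "average")
  du <- u - mean(u)
  dv <- v - mean(v)
  den <- sqrt(sum(du^2) * sum(dv^2))
  if (den == 0) return(NA_real_)
  sum(du * dv) / den
}

#' Area under the ROC curve for binarized disorder
#'
#' Order (truth score > 8) is the positive class; the AUC is the probability
#' that a randomly chosen ordered residue receives a higher predictive value
#' than a randomly chosen disordered one. Computed via rank statistics in
#' O(m log m). Two tie conventions are available: `"half"` (ties between the
#' classes contribute 1/2, the usual toolkit convention, default) and
#' `"strict"` (ties contribute 0, the literal pairwise indicator). The two
#' differ by exactly `n_tied_pairs / (2 * m_plus * m_minus)`.
#'
#' @param pred numeric predictive values (higher = more ordered).
#' @param is_positive logical vector; `TRUE` for the positive (ordered) class.
#' @param ties `"half"` or `"strict"`.
#' @return AUC in \[0, 1\], or `NA_real_` if only one class is present.
#' @export
auc <- function(pred, is_positive, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  stopifnot(length(pred) == length(is_positive), is.logical(is_positive))
  m_plus <- sum(is_positive)
  m_minus <- sum(!is_positive)
  if (m_plus == 0L || m_minus == 0L) return(NA_real_)
  r <- rank(pred, ties.method = "average")
  a <- (sum(r[is_positive]) - m_plus * (m_plus + 1) / 2) / (m_plus * m_minus)
  if (ties == "strict") {
    a <- a - n_tied_cross_pairs(pred, is_positive) / (2 * m_plus * m_minus)
  }
  a
}

# Number of (positive, negative) pairs with identical predictive value.
n_tied_cross_pairs <- function(pred, is_positive) {
  tp <- table(pred[is_positive])
  tn <- table(pred[!is_positive])
  common <- intersect(names(tp), names(tn))
  if (!length(common)) return(0)
  sum(as.numeric(tp[common]) * as.numeric(tn[common]))
}

#' Bootstrap mean and 95% confidence interval of a paired statistic
#'
#' Draws `n_sets` resamples of size m (the number of residue pairs) with
#' replacement, computes the statistic on each, and summarizes: the reported
#' value is the mean over the resamples and the CI halfwidth is 1.96 times
#' their population (divide-by-n) standard deviation. Resamples on which the
#' statistic is undefined (`NA`) are dropped and counted.
#'
#' @param stat function `(truth, pred) -> numeric` (e.g. [spearman_rho()]).
#' @param truth,pred paired numeric vectors.
#' @param n_sets number of bootstrap sets, default 1000.
#' @param seed integer RNG seed.
#' @param protein_ids optional id per pair; when given, whole proteins are
#'   resampled with replacement instead of residues.
#' @return A list of class `bootstrap_result`: `mean_stat`,
#'   `ci95_halfwidth`, `sd`, `n_sets`, `per_set_stats`, `n_dropped`.
#' @export
bootstrap_stat <- function(stat, truth, pred, n_sets = 1000L, seed = 42L,
                           protein_ids = NULL) {
  stopifnot(length(truth) == length(pred), n_sets >= 2L)
  set.seed(as.integer(seed))
  m <- length(truth)
  draws <- vapply(seq_len(n_sets), function(s) {
    idx <- if (is.null(protein_ids)) {
      sample.int(m, m, replace = TRUE)
    } else {
      uid <- unique(protein_ids)
      picked <- sample(uid, length(uid), replace = TRUE)
      unlist(lapply(picked, function(id) which(protein_ids == id)),
             use.names = FALSE)
    }
    stat(truth[idx], pred[idx])
  }, 0.0)
  ok <- !is.na(draws)
  if (!any(ok)) stop("statistic undefined on every bootstrap set")
  x <- draws[ok]
  sd_pop <- sqrt(mean((x - mean(x))^2))
  structure(list(mean_stat = mean(x),
                 ci95_halfwidth = 1.96 * sd_pop,
                 sd = sd_pop,
                 n_sets = as.integer(n_sets),
                 per_set_stats = x,
                 n_dropped = sum(!ok)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap mean %.4f +/- %.4f (95%% CI, %d sets, %d dropped)\n",
              x$mean_stat, x$ci95_halfwidth, x$n_sets, x$n_dropped))
  invisible(x)
}

#' Receiver operating characteristic curve
#'
#' Sweeps the decision threshold over the predictive values (descending,
#' tied values grouped) and reports the monotone staircase from (0, 0) to
#' (1, 1). Its trapezoidal area equals [auc()] with the ties-as-half
#' convention.
#'
#' @inheritParams auc
#' @return A data.frame with columns `threshold`, `fpr`, `tpr`, beginning at
#'   (0, 0) with `threshold = Inf`.
#' @export
roc_curve <- function(pred, is_positive) {
  stopifnot(length(pred) == length(is_positive), is.logical(is_positive))
  m_plus <- sum(is_positive)
  m_minus <- sum(!is_positive)
  if (m_plus == 0L || m_minus == 0L) {
    stop("roc_curve requires both classes present")
  }
  o <- order(pred, decreasing = TRUE)
  p <- pred[o]
  lab <- is_positive[o]
  grp_end <- which(c(p[-1] != p[-length(p)], TRUE))
  tp <- cumsum(lab)[grp_end]
  fp <- cumsum(!lab)[grp_end]
  data.frame(threshold = c(Inf, p[grp_end]),
             fpr = c(0, fp / m_minus),
             tpr = c(0, tp / m_plus))
}

#' Trapezoidal area under a ROC curve
#' @param roc data.frame from [roc_curve()].
#' @return Numeric area.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

#' Evaluate predictions against ground-truth records
#'
#' Pools residues with valid CheZOD scores across proteins and reports the
#' Spearman correlation and AUC (order = positive class after binarizing the
#' truth at 8), each with its plug-in value and bootstrap mean and 95% CI,
#' plus the ROC curve. Optionally stratifies the correlation by the
#' three-class region taxonomy of [classify_regions()].
#'
#' @param records list of [protein_record()]s with ground-truth scores.
#' @param predictions named list of numeric vectors; each either full
#'   protein length (invalid residues are dropped by the truth mask) or
#'   already filtered length.
#' @param n_boot bootstrap sets, default 1000.
#' @param seed RNG seed for the bootstrap.
#' @param per_class also evaluate the ordered / short-disorder /
#'   long-disorder residue subsets, default `FALSE`.
#' @param higher_is_disorder set `TRUE` for predictors whose large values
#'   mean disorder (e.g. nothing to negate for pLDDT, but `TRUE` for a raw
#'   disorder probability); such predictions are negated before rho/AUC.
#' @return A list of class `eval_report`.
#' @export
evaluate_predictions <- function(records, predictions, n_boot = 1000L,
                                 seed = 42L, per_class = FALSE,
                                 higher_is_disorder = FALSE) {
  truth <- numeric(0); pred <- numeric(0); pid <- character(0)
  bad <- character(0)
  for (rec in records) {
    pv <- predictions[[rec$id]]
    if (is.null(pv)) { bad <- c(bad, rec$id); next }
    keep <- rec$valid_mask
    if (length(pv) == length(rec$scores)) {
      pv <- pv[keep]
    } else if (length(pv) != sum(keep)) {
      bad <- c(bad, rec$id); next
    }
    truth <- c(truth, rec$scores[keep])
    pred <- c(pred, pv)
    pid <- c(pid, rep(rec$id, sum(keep)))
  }
  if (length(bad)) {
    stop(sprintf("missing or length-mismatched predictions for: %s",
                 paste(bad, collapse = ", ")))
  }
  if (higher_is_disorder) pred <- -pred
  is_ordered <- truth > CHEZOD_DISORDER_THRESHOLD

  rho_boot <- bootstrap_stat(spearman_rho, truth, pred,
                             n_sets = n_boot, seed = seed)
  auc_stat <- function(t, p) auc(p, t > CHEZOD_DISORDER_THRESHOLD)
  auc_boot <- bootstrap_stat(auc_stat, truth, pred,
                             n_sets = n_boot, seed = seed + 1L)
  report <- list(
    n_residues = length(truth),
    n_proteins = length(records),
    rho = spearman_rho(truth, pred),
    rho_boot = rho_boot,
    auc = auc(pred, is_ordered),
    auc_boot = auc_boot,
    roc = roc_curve(pred, is_ordered)
  )
  if (per_class) {
    cls <- unlist(lapply(records, function(rec) {
      classify_regions(rec$scores[rec$valid_mask])
    }), use.names = FALSE)
    report$per_class <- lapply(
      stats::setNames(nm = c("ORDERED", "SHORT_DISORDER", "LONG_DISORDER")),
      function(lv) {
        i <- cls == lv
        if (sum(i) < 2L) return(NULL)
        list(n = sum(i),
             rho = spearman_rho(truth[i], pred[i]),
             rho_boot = bootstrap_stat(spearman_rho, truth[i], pred[i],
                                       n_sets = n_boot, seed = seed + 2L))
      })
  }
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d residues in %d proteins\n",
              x$n_residues, x$n_proteins))
  cat(sprintf("  Spearman rho: %.3f (bootstrap %.3f +/- %.3f)\n",
              x$rho, x$rho_boot$mean_stat, x$rho_boot$ci95_halfwidth))
  cat(sprintf("  AUC (order positive): %.3f (bootstrap %.3f +/- %.3f)\n",
              x$auc, x$auc_boot$mean_stat, x$auc_boot$ci95_halfwidth))
  if (!is.null(x$per_class)) {
    for (nm in names(x$per_class)) {
      pc <- x$per_class[[nm]]
      if (is.null(pc)) next
      cat(sprintf("  %-14s n=%6d rho=%.3f +/- %.3f\n", nm, pc$n,
                  pc$rho_boot$mean_stat, pc$rho_boot$ci95_halfwidth))
    }
  }
  invisible(x)
}
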