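#' Extract per-residue pLDDT values from an AlphaFold2 model PDB file
#'
#' AlphaFold2 model files carry the per-residue pLDDT (0-100) in the
#' B-factor column, identical for all atoms of a residue. Reads ATOM records
#' of the first chain via bio3d, asserts within-residue agreement and
#' returns one value per residue in file order.
#'
#' @param path single-model PDB file.
#' @param tol maximum within-residue B-factor spread tolerated, default 1e-3.
#' @return Numeric vector of per-residue pLDDT values.
#' @export
extract_plddt <- function(path, tol = 1e-3) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  n_models <- sum(grepl("^MODEL ", readLines(path, warn = FALSE)))
  if (n_models > 1L) {
    stop(sprintf("%s: multi-model PDB (%d MODEL records); expected one",
                 path, n_models))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (nrow(at) == 0L) stop(sprintf("%s: no ATOM records", path))
  at <- at[at$chain == at$chain[1L], ]
  resno <- at$resno
  # residues in order of first appearance
  keys <- unique(resno)
  vapply(keys, function(rn) {
    b <- at$b[resno == rn]
    if (max(b) - min(b) > tol) {
      stop(sprintf("%s: residue %d has inconsistent B-factors (%.3f..%.3f)",
                   path, rn, min(b), max(b)))
    }
    b[1L]
  }, 0.0)
}

#' Sliding-window mean with asymmetric edge shrinking
#'
#' Position i averages the window `[i - h, i + h]` with `h = (window - 1)/2`
#' clipped at the termini: near an end, the terminus side shrinks to the
#' positions that exist while the other side keeps its `h` positions
#' (truncated at the opposite terminus for sequences shorter than the
#' window). `window = 1` is the identity.
#'
#' @param values numeric vector.
#' @param window odd window length, e.g. 21 for pLDDT, 25 for RSA.
#' @return Numeric vector of the same length; every output lies within the
#'   min/max of its window.
#' @export
smooth_scores <- function(values, window) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  L <- length(values)
  if (L == 0L) stop("empty input")
  if (window == 1L) return(values)
  h <- (window - 1L) %/% 2L
  lo <- pmax(1L, seq_len(L) - h)
  hi <- pmin(L, seq_len(L) + h)
  cs <- c(0, cumsum(values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Bundle per-residue structural disorder proxies for one protein
#'
#' @param protein_id identifier.
#' @param plddt numeric vector in \[0, 100\].
#' @param rsa optional relative solvent accessibility in \[0, 1\].
#' @param exp_res optional "experimentally resolved" probability in \[0, 1\].
#' @return A list of class `residue_structural_measures`; all present
#'   vectors must share one length.
#' @export
residue_structural_measures <- function(protein_id, plddt, rsa = NULL,
                                        exp_res = NULL) {
  stopifnot(is.numeric(plddt), all(plddt >= 0 & plddt <= 100))
  for (v in list(rsa, exp_res)) {
    if (!is.null(v)) {
      stopifnot(length(v) == length(plddt), all(v >= 0 & v <= 1))
    }
  }
  structure(list(protein_id = protein_id, plddt = plddt,
                 rsa = rsa, exp_res = exp_res),
            class = "residue_structural_measures")
}

#' Derive the smoothed AlphaFold2 disorder proxies
#'
#' Emits the raw pLDDT, the pLDDT smoothed over 21 consecutive residues, the
#' RSA smoothed over 25 residues (when present) and the "experimentally
#' resolved" values (pass-through). The orientation metadata records, for
#' each proxy, whether low values indicate disorder — needed to orient the
#' proxy before rho/AUC evaluation: low pLDDT, low exp_res and low *negated*
#' RSA (i.e. high RSA) all indicate disorder.
#'
#' @param measures a [residue_structural_measures()].
#' @param plddt_window smoothing window for pLDDT, default 21.
#' @param rsa_window smoothing window for RSA, default 25.
#' @return A list of class `smoothed_measures` with per-proxy value vectors
#'   and an `orientation` list (`"low_is_disorder"` / `"high_is_disorder"`).
#' @export
smoothed_measures <- function(measures, plddt_window = 21L, rsa_window = 25L) {
  stopifnot(inherits(measures, "residue_structural_measures"))
  out <- list(protein_id = measures$protein_id,
              plddt = measures$plddt,
              plddt_smoothed = smooth_scores(measures$plddt, plddt_window))
  orientation <- list(plddt = "low_is_disorder",
                      plddt_smoothed = "low_is_disorder")
  if (!is.null(measures$rsa)) {
    out$rsa_smoothed <- smooth_scores(measures$rsa, rsa_window)
    orientation$rsa_smoothed <- "high_is_disorder"
  }
  if (!is.null(measures$exp_res)) {
    out$exp_res <- measures$exp_res
    orientation$exp_res <- "low_is_disorder"
  }
  out$orientation <- orientation
  structure(out, class = "smoothed_measures")
}

#' Read a per-residue value table (RSA or "experimentally resolved")
#'
#' Expects a TSV with columns `protein_id`, `residue_index` (1-based,
#' contiguous per protein) and `value`.
#'
#' @param path TSV path.
#' @return Named list of numeric vectors, one per protein.
#' @export
read_residue_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "residue_index", "value")
  if (!all(need %in% names(tab))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  out <- lapply(split(tab, tab$protein_id), function(d) {
    d <- d[order(d$residue_index), ]
    if (!identical(as.integer(d$residue_index), seq_len(nrow(d)))) {
      stop(sprintf("%s: protein '%s': residue indices not 1-based contiguous",
                   path, d$protein_id[1L]))
    }
    d$value
  })
  out
}

#' Cost/gain analysis of disorder predictions as an AlphaFold2 pre-filter
#'
#' Given per-protein mean predicted CheZOD scores and per-protein mean
#' pLDDTs, sweeps a threshold t over the mean predicted score and reports,
#' per threshold, what filtering out proteins with mean score < t would
#' cost and save. Writing P for the proteins with mean pLDDT >= `plddt_cutoff`
#' (the "wanted" well-predicted set), FN for filtered-out proteins that are
#' wanted, TN for filtered-out unwanted proteins and TP for retained wanted
#' proteins: cost = FN/P (wanted structures missed), gain = (FN+TN)/All
#' (structure predictions avoided) and accuracy = (TP+TN)/All.
#'
#' @param mean_pred named numeric vector of per-protein mean predicted
#'   CheZOD scores.
#' @param mean_plddt named numeric vector of per-protein mean pLDDTs over
#'   the same protein ids.
#' @param thresholds numeric vector of mean-score cutoffs t (strict:
#'   a protein is filtered out when its mean score is < t).
#' @param plddt_cutoff mean-pLDDT cutoff defining wanted proteins,
#'   default 70.
#' @return A data.frame with columns `threshold`, `cost`, `gain`,
#'   `accuracy`; `cost` is `NA` when no protein reaches the pLDDT cutoff.
#' @export
prefilter_analysis <- function(mean_pred, mean_plddt, thresholds,
                               plddt_cutoff = 70) {
  ids <- names(mean_pred)
  if (is.null(ids) || is.null(names(mean_plddt)) ||
      !setequal(ids, names(mean_plddt))) {
    stop("mean_pred and mean_plddt must be named over the same protein ids")
  }
  mean_plddt <- mean_plddt[ids]
  all_n <- length(ids)
  wanted <- mean_plddt >= plddt_cutoff
  P <- sum(wanted)
  rows <- lapply(sort(thresholds), function(t) {
    filtered <- mean_pred < t
    FN <- sum(filtered & wanted)
    TN <- sum(filtered & !wanted)
    TP <- sum(!filtered & wanted)
    data.frame(threshold = t,
               cost = if (P > 0L) FN / P else NA_real_,
               gain = (FN + TN) / all_n,
               accuracy = (TP + TN) / all_n)
  })
  do.call(rbind, rows)
}
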