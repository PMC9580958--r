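#' The fixed 9 bin edges of the organism disorder spectrum
#'
#' Eight bins over predicted CheZOD scores from -15 to 16.
#' @export
SPECTRUM_BIN_EDGES <- c(-15, -11.125, -7.25, -3.375, 0.5, 4.375, 8.25,
                        12.125, 16)

#' Build the 8-bin disorder spectrum of one organism
#'
#' Counts all predicted per-residue CheZOD scores of an organism into eight
#' fixed bins and normalizes by the number of binned residues. Bins are
#' half-open `[edge_i, edge_{i+1})` with the final bin closed at 16.
#' Proteins longer than `max_len` residues are excluded (and counted).
#' Scores outside `[-15, 16]` are clipped to the nearest edge when
#' `clip = TRUE` (default; predictions can exceed the training range),
#' otherwise dropped with a warning.
#'
#' @param scores_per_protein list of numeric vectors, one per protein.
#' @param organism_id identifier string.
#' @param max_len maximum protein length included, default 9000.
#' @param clip clip out-of-range scores instead of dropping, default `TRUE`.
#' @return A list of class `organism_spectrum` with `organism_id`,
#'   `bin_edges`, `counts` (8 integers), `normalized` (sums to 1 with
#'   clipping), `n_residues`, `n_excluded_long`.
#' @export
build_spectrum <- function(scores_per_protein, organism_id,
                           max_len = 9000L, clip = TRUE) {
  stopifnot(is.list(scores_per_protein), length(scores_per_protein) > 0L)
  lens <- lengths(scores_per_protein)
  keep <- lens <= max_len
  n_excluded <- sum(!keep)
  if (!any(keep)) {
    stop(sprintf("organism '%s': all %d proteins exceed max_len %d",
                 organism_id, length(lens), max_len))
  }
  s <- unlist(scores_per_protein[keep], use.names = FALSE)
  edges <- SPECTRUM_BIN_EDGES
  if (clip) {
    s <- pmin(pmax(s, edges[1L]), edges[length(edges)])
  } else {
    out <- s < edges[1L] | s > edges[length(edges)]
    if (any(out)) {
      warning(sprintf("organism '%s': dropped %d scores outside [%g, %g]",
                      organism_id, sum(out), edges[1L], edges[length(edges)]))
      s <- s[!out]
    }
  }
  # [edge_i, edge_{i+1}) bins, last bin closed at the right edge
  idx <- findInterval(s, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = 8L)
  structure(list(organism_id = organism_id,
                 bin_edges = edges,
                 counts = counts,
                 normalized = counts / length(s),
                 n_residues = length(s),
                 n_excluded_long = n_excluded),
            class = "organism_spectrum")
}

#' @export
print.organism_spectrum <- function(x, ...) {
  cat(sprintf("<organism_spectrum> %s: %d residues (%d long proteins excluded)\n",
              x$organism_id, x$n_residues, x$n_excluded_long))
  print(round(x$normalized, 4))
  invisible(x)
}

#' Project organism disorder spectra by principal component analysis
#'
#' Centers the 8-dimensional normalized spectra (no variance scaling,
#' matching `prcomp` defaults) and extracts the top-k components via
#' singular value decomposition. Loadings follow a deterministic sign
#' convention: each loading vector's largest-magnitude entry is positive.
#'
#' @param spectra list of [build_spectrum()] results, length >= 2.
#' @param k number of components, default 2, at most 8 and at most
#'   `length(spectra) - 1`.
#' @return A list of class `pca_projection` with `organism_ids`, `scores`
#'   (organisms x k), `explained_variance_fractions` (all components) and
#'   `loadings` (8 x k).
#' @export
pca_project <- function(spectra, k = 2L) {
  stopifnot(length(spectra) >= 2L)
  k <- as.integer(k)
  if (k < 1L || k > 8L) stop("k must be in 1..8")
  if (k > length(spectra) - 1L) {
    stop(sprintf("k = %d exceeds number of organisms - 1 = %d",
                 k, length(spectra) - 1L))
  }
  X <- do.call(rbind, lapply(spectra, `[[`, "normalized"))
  ids <- vapply(spectra, `[[`, "", "organism_id")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  evf <- if (sum(vars) > 0) vars / sum(vars) else rep(0, length(vars))
  nk <- min(k, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(nk), drop = FALSE]
  scores <- pc$x[, seq_len(nk), drop = FALSE]
  for (j in seq_len(nk)) {           # sign convention
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- ids
  structure(list(organism_ids = ids,
                 scores = scores,
                 explained_variance_fractions = evf,
                 loadings = load),
            class = "pca_projection")
}

#' Write spectra and a PCA projection to TSV files
#'
#' @param spectra list of [build_spectrum()] results.
#' @param projection a [pca_project()] result.
#' @param out_prefix path prefix; writes `<prefix>_spectra.tsv` and
#'   `<prefix>_projection.tsv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_spectrum_tables <- function(spectra, projection, out_prefix) {
  sp <- data.frame(organism = vapply(spectra, `[[`, "", "organism_id"),
                   do.call(rbind, lapply(spectra, `[[`, "normalized")),
                   n_residues = vapply(spectra, `[[`, 0L, "n_residues"))
  names(sp)[2:9] <- paste0("bin", 1:8)
  f1 <- paste0(out_prefix, "_spectra.tsv")
  utils::write.table(sp, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  pr <- data.frame(organism = projection$organism_ids, projection$scores)
  f2 <- paste0(out_prefix, "_projection.tsv")
  con <- file(f2, "wt")
  writeLines(paste0("# explained variance fractions: ",
                    paste(sprintf("%.6f", projection$explained_variance_fractions),
                          collapse = " ")), con)
  utils::write.table(pr, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(c(f1, f2))
}
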