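#' Configuration for the synthetic embedding/score generator
#'
#' The generator plants the three statistical structures the disorder models
#' exploit in real embeddings: (1) a single dominant disorder-informative
#' embedding dimension, (2) per-amino-acid cluster structure, and
#' (3) contiguous disordered regions produced by smoothing a latent signal.
#'
#' @param n_proteins number of proteins to generate.
#' @param length_mean mean protein length (default 112, the scale of typical
#'   NMR-amenable proteins); lengths follow a shifted geometric distribution
#'   truncated to \[20, 1000\].
#' @param dim embedding dimension N (default 1024).
#' @param informative_dim_index 1-based index of the planted disorder
#'   dimension (default 295).
#' @param signal_weight weight of the latent disorder signal in the
#'   informative dimension (default 1).
#' @param noise_sd i.i.d. Gaussian noise SD added to every embedding entry
#'   (default 1).
#' @param aa_cluster_scale weight of the per-amino-acid centroid vectors
#'   (default 1).
#' @param order_fraction_target expected fraction of residues with score > 8
#'   (default 0.72, the composition of a typical training set).
#' @param region_smoothing moving-average window (residues) applied to the
#'   latent signal; larger values produce longer contiguous
#'   ordered/disordered regions (default 15).
#' @param target_window when > 1, the true score depends on a moving average
#'   of the latent signal over this many residues while the embedding carries
#'   the per-residue signal, so sequence context is required for optimal
#'   prediction (default 1).
#' @param score_sd SD of the affine score map before clipping (default 4).
#' @param id_prefix prefix of the generated protein ids (default `"SYN"`);
#'   use distinct prefixes when combining several generated sets.
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins,
                             length_mean = 112L,
                             dim = 1024L,
                             informative_dim_index = 295L,
                             signal_weight = 1,
                             noise_sd = 1,
                             aa_cluster_scale = 1,
                             order_fraction_target = 0.72,
                             region_smoothing = 15L,
                             target_window = 1L,
                             score_sd = 4,
                             id_prefix = "SYN",
                             seed = 42L) {
  stopifnot(n_proteins >= 1L, length_mean > 20L, dim >= 1L,
            informative_dim_index >= 1L, informative_dim_index <= dim,
            is.finite(signal_weight), signal_weight >= 0,
            is.finite(noise_sd), noise_sd >= 0,
            is.finite(aa_cluster_scale), aa_cluster_scale >= 0,
            region_smoothing >= 1L, target_window >= 1L, score_sd > 0)
  if (order_fraction_target <= 0 || order_fraction_target >= 1) {
    stop("order_fraction_target must lie strictly in (0, 1)")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# Observed CheZOD score range used for clipping
CHEZOD_SCORE_MIN <- -5.6
CHEZOD_SCORE_MAX <- 16.2

# Moving average over a clipped centered window, rescaled per position so the
# result is exactly standard normal when the input is i.i.d. N(0,1).
standardized_moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  L <- length(x)
  h <- (window - 1L) %/% 2L
  lo <- pmax(1L, seq_len(L) - h)
  hi <- pmin(L, seq_len(L) + h + (window - 1L) %% 2L)
  cs <- c(0, cumsum(x))
  k <- hi - lo + 1L
  (cs[hi + 1L] - cs[lo]) / sqrt(k)
}

#' Generate a seeded synthetic dataset of proteins, scores and embeddings
#'
#' For each protein a latent disorder signal is produced by moving-averaging
#' i.i.d. Gaussian noise (creating contiguous regions), mapped affinely to
#' CheZOD-like scores calibrated so the expected fraction of scores > 8
#' equals `order_fraction_target`, and clipped to the observed score range
#' \[-5.6, 16.2\]. Embedding row i is
#' `aa_cluster_scale * c(aa_i) + signal_weight * z_i * u + eps_i` with fixed
#' per-amino-acid centroids `c`, `u` the unit vector along the informative
#' dimension and i.i.d. Gaussian noise `eps`. The affine map and planted
#' direction are returned for recovery tests.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `records` (list of [protein_record()]),
#'   `embeddings` (named list of [embedding_matrix()]) and `params`
#'   (`u_index`, affine coefficients `a`, `b`, centroid matrix, config).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  a <- config$score_sd
  b <- CHEZOD_DISORDER_THRESHOLD + a * stats::qnorm(config$order_fraction_target)
  if (b <= CHEZOD_SCORE_MIN || b >= CHEZOD_SCORE_MAX) {
    stop(sprintf(
      "order_fraction_target %.3f unreachable under clipping to [%.1f, %.1f]",
      config$order_fraction_target, CHEZOD_SCORE_MIN, CHEZOD_SCORE_MAX))
  }
  set.seed(config$seed)
  centroids <- matrix(stats::rnorm(20L * config$dim), nrow = 20L,
                      dimnames = list(AA_ALPHABET, NULL))
  centroids <- centroids / sqrt(rowSums(centroids^2))  # unit-norm rows

  p <- 1 / (config$length_mean - 20L + 1L)
  lengths <- pmin(20L + stats::rgeom(config$n_proteins, p), 1000L)

  z_lo <- (CHEZOD_SCORE_MIN - b) / a
  z_hi <- (CHEZOD_SCORE_MAX - b) / a
  ids <- sprintf("%s%04d", config$id_prefix, seq_len(config$n_proteins))
  records <- vector("list", config$n_proteins)
  embeddings <- vector("list", config$n_proteins)
  for (j in seq_len(config$n_proteins)) {
    L <- lengths[j]
    raw <- stats::rnorm(L)
    z <- standardized_moving_average(raw, config$region_smoothing)
    t <- if (config$target_window > 1L) {
      standardized_moving_average(z, config$target_window)
    } else z
    scores <- a * pmin(pmax(t, z_lo), z_hi) + b
    zc <- pmin(pmax(z, z_lo), z_hi)   # embedding carries the clipped signal
    aa <- sample(AA_ALPHABET, L, replace = TRUE)
    E <- config$noise_sd * matrix(stats::rnorm(L * config$dim), nrow = L)
    if (config$aa_cluster_scale > 0) {
      E <- E + config$aa_cluster_scale * centroids[aa, , drop = FALSE]
    }
    E[, config$informative_dim_index] <-
      E[, config$informative_dim_index] + config$signal_weight * zc
    dimnames(E) <- NULL
    records[[j]] <- protein_record(ids[j], paste0(aa, collapse = ""), scores)
    embeddings[[j]] <- embedding_matrix(E, protein_id = ids[j])
  }
  names(embeddings) <- ids
  list(records = records,
       embeddings = embeddings,
       params = list(u_index = config$informative_dim_index, a = a, b = b,
                     centroids = centroids, config = config))
}

#' Generate AlphaFold2-style pLDDT fixtures coupled to CheZOD scores
#'
#' Produces one per-residue pLDDT vector per protein as a monotone affine
#' transform of its CheZOD scores (the observed score range \[-5.6, 16.2\]
#' maps onto \[0, 100\]) mixed with noise: at `coupling = 1` the map is exact
#' and strictly monotone, so both per-residue values and per-protein means
#' agree with the scores in rank; at `coupling = 0` the values are
#' independent of the scores. Optionally writes single-chain
#' poly-alanine PDB files whose B-factor column carries the pLDDT (identical
#' for all atoms of a residue), as AlphaFold2 model files do.
#'
#' @param records list of [protein_record()]s.
#' @param coupling real in \[0, 1\]; strength of the score/pLDDT association.
#' @param seed integer RNG seed.
#' @param dir optional directory; when given, one `<id>.pdb` file per protein
#'   is written there.
#' @param noise_sd SD of the additive noise at `coupling = 0` (default 20).
#' @return A list with `plddt` (named list of numeric vectors, rounded to the
#'   2 decimals a PDB B-factor carries) and `pdb_files` (named character
#'   vector of paths, or `NULL`).
#' @export
generate_af2_fixture <- function(records, coupling, seed, dir = NULL,
                                 noise_sd = 20) {
  stopifnot(length(records) > 0L, coupling >= 0, coupling <= 1)
  set.seed(as.integer(seed))
  plddt <- lapply(records, function(rec) {
    s <- rec$scores
    signal <- 100 * (s - CHEZOD_SCORE_MIN) /
      (CHEZOD_SCORE_MAX - CHEZOD_SCORE_MIN)
    mu <- coupling * signal + (1 - coupling) * 50
    v <- mu + (1 - coupling) * noise_sd * stats::rnorm(length(s))
    round(pmin(pmax(v, 0), 100), 2L)
  })
  names(plddt) <- vapply(records, `[[`, "", "id")
  pdb_files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pdb_files <- vapply(names(plddt), function(id) {
      f <- file.path(dir, paste0(id, ".pdb"))
      write_minimal_pdb(plddt[[id]], f)
      f
    }, "")
  }
  list(plddt = plddt, pdb_files = pdb_files)
}

# Single-model single-chain poly-alanine backbone; B-factor = per-residue value.
write_minimal_pdb <- function(bfactors, path) {
  atoms <- c("N", "CA", "C", "O")
  offs <- matrix(c(0, 0, 0, 1.46, 0, 0, 2.0, 1.4, 0, 2.0, 2.6, 0),
                 ncol = 3L, byrow = TRUE)
  lines <- character(0)
  ser <- 0L
  for (i in seq_along(bfactors)) {
    for (k in seq_along(atoms)) {
      ser <- ser + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        ser, atoms[k], "ALA", "A", i,
        (i - 1) * 3.8 + offs[k, 1L], offs[k, 2L], offs[k, 3L],
        1.0, bfactors[i]))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
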