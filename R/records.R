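#' @keywords internal
"_PACKAGE"

# Sentinel convention: any CheZOD score >= 900 marks a residue without a
# valid experimental score.
CHEZOD_SENTINEL <- 900

#' Binarization threshold between disorder and order
#'
#' Residues with CheZOD score <= 8 are conventionally disordered, > 8 ordered.
#' @export
CHEZOD_DISORDER_THRESHOLD <- 8

#' The 20 standard amino acids in alphabetical one-letter order
#'
#' This fixed order defines the columns of [one_hot_encode()] matrices.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a protein record
#'
#' A protein record bundles an identifier, an amino-acid sequence (20 standard
#' letters plus `X` for unknown) and per-residue CheZOD scores aligned 1:1
#' with the sequence. Scores `>= 900` are sentinels for residues without a
#' valid experimental score; `valid_mask` is derived from them.
#'
#' @param id single string, protein identifier.
#' @param sequence single string over `A..Y` plus `X`. Non-standard letters
#'   `B`, `Z`, `U`, `O` are mapped to `X` with a warning.
#' @param scores numeric vector, one CheZOD score per residue.
#' @return An object of class `protein_record` with fields `id`, `sequence`,
#'   `scores` and `valid_mask` (`FALSE` exactly where `scores >= 900`).
#' @examples
#' rec <- protein_record("P1", "ACD", c(5, 900, 7.2))
#' rec$valid_mask
#' @export
protein_record <- function(id, sequence, scores) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  sequence <- map_nonstandard_aa(sequence)
  scores <- as.numeric(scores)
  if (nchar(sequence) != length(scores)) {
    stop(sprintf("protein '%s': sequence length %d != number of scores %d",
                 id, nchar(sequence), length(scores)))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% c(AA_ALPHABET, "X")))
  if (length(bad) > 0L) {
    stop(sprintf("protein '%s': invalid character '%s' at position %d",
                 id, chars[bad[1L]], bad[1L]))
  }
  structure(
    list(id = id, sequence = sequence, scores = scores,
         valid_mask = scores < CHEZOD_SENTINEL),
    class = "protein_record"
  )
}

# B/Z/U/O (ambiguous or rare residues) -> X, matching common pLM preprocessing
map_nonstandard_aa <- function(sequence) {
  if (grepl("[BZUO]", sequence)) {
    warning("non-standard residue letters (B/Z/U/O) mapped to 'X'")
    sequence <- chartr("BZUO", "XXXX", sequence)
  }
  sequence
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d residues (%d valid)\n",
              x$id, length(x$scores), sum(x$valid_mask)))
  invisible(x)
}

#' @export
length.protein_record <- function(x) length(x$scores)

#' Drop residues without a valid CheZOD score
#'
#' Removes all positions whose score is a sentinel (`>= 900`), shortening
#' sequence and scores consistently and preserving residue order. Idempotent.
#'
#' @param record a [protein_record()].
#' @return A `protein_record` containing only valid residues. An all-invalid
#'   input yields an empty record with a warning.
#' @export
filter_invalid <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  keep <- record$valid_mask
  if (all(keep)) return(record)
  if (!any(keep)) {
    warning(sprintf("protein '%s': all residues invalid; returning empty record",
                    record$id))
  }
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  structure(
    list(id = record$id,
         sequence = paste0(chars[keep], collapse = ""),
         scores = record$scores[keep],
         valid_mask = rep(TRUE, sum(keep))),
    class = "protein_record"
  )
}

#' Binarize CheZOD scores into order/disorder
#'
#' Scores `<= threshold` (default 8) are `"disorder"`, scores above are
#' `"order"`.
#'
#' @param scores numeric vector of valid CheZOD scores (no sentinels).
#' @param threshold numeric cutoff, default 8.
#' @return Character vector of `"order"` / `"disorder"`, same length.
#' @export
binarize <- function(scores, threshold = CHEZOD_DISORDER_THRESHOLD) {
  scores <- as.numeric(scores)
  if (any(scores >= CHEZOD_SENTINEL, na.rm = TRUE)) {
    stop("sentinel scores (>= 900) present; apply filter_invalid() first")
  }
  ifelse(scores <= threshold, "disorder", "order")
}

#' Three-class per-residue disorder taxonomy
#'
#' Partitions residues into `ORDERED` (score > theta), `LONG_DISORDER`
#' (residue lies in a maximal run of consecutive scores <= theta of length
#' >= `lmin`) and `SHORT_DISORDER` (in a shorter such run). Every residue
#' receives exactly one label, and the disordered labels coincide with
#' [binarize()]'s `"disorder"` class.
#'
#' @param scores numeric vector of valid CheZOD scores.
#' @param theta disorder threshold, default 8.
#' @param lmin minimum run length of a long disordered region, default 30.
#' @return Character vector over `{"ORDERED", "SHORT_DISORDER", "LONG_DISORDER"}`.
#' @export
classify_regions <- function(scores, theta = CHEZOD_DISORDER_THRESHOLD,
                             lmin = 30L) {
  lmin <- as.integer(lmin)
  if (is.na(lmin) || lmin < 1L) stop("lmin must be an integer >= 1")
  scores <- as.numeric(scores)
  if (length(scores) == 0L) return(character(0))
  if (any(scores >= CHEZOD_SENTINEL)) {
    stop("sentinel scores (>= 900) present; apply filter_invalid() first")
  }
  dis <- scores <= theta
  r <- rle(dis)
  run_lab <- ifelse(!r$values, "ORDERED",
                    ifelse(r$lengths >= lmin, "LONG_DISORDER", "SHORT_DISORDER"))
  rep(run_lab, r$lengths)
}

#' One-hot encode an amino-acid sequence
#'
#' Each standard residue maps to a 20-dimensional indicator row; the columns
#' follow [AA_ALPHABET] (alphabetical one-letter codes). The unknown residue
#' `X` maps to an all-zero row.
#'
#' @param sequence single string over the 20 standard letters plus `X`.
#' @param protein_id identifier stored in the returned matrix attributes.
#' @return An `embedding_matrix` (L x 20 numeric matrix with column names
#'   [AA_ALPHABET] and attributes `protein_id`, `dim`).
#' @export
one_hot_encode <- function(sequence, protein_id = "") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% c(AA_ALPHABET, "X")))
  if (length(bad) > 0L) {
    stop(sprintf("invalid character '%s' at position %d", chars[bad[1L]], bad[1L]))
  }
  m <- matrix(0, nrow = length(chars), ncol = 20L,
              dimnames = list(NULL, AA_ALPHABET))
  idx <- match(chars, AA_ALPHABET)      # NA for 'X' -> row stays zero
  hit <- which(!is.na(idx))
  m[cbind(hit, idx[hit])] <- 1
  embedding_matrix(m, protein_id = protein_id)
}

#' Construct an embedding matrix
#'
#' An L x N numeric matrix of per-residue features (rows = residues, columns =
#' embedding dimensions), tagged with its protein id.
#'
#' @param values numeric matrix, all entries finite.
#' @param protein_id identifier string.
#' @return The matrix with class `embedding_matrix` and attribute `protein_id`.
#' @export
embedding_matrix <- function(values, protein_id = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(values) && !all(is.finite(values))) {
    stop(sprintf("embedding for '%s' contains non-finite values", protein_id))
  }
  structure(values, protein_id = protein_id,
            class = c("embedding_matrix", "matrix", "array"))
}
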