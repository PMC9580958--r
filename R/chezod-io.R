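#' Read a CheZOD score file
#'
#' Parses the canonical per-residue CheZOD dialect: one stanza per protein,
#' consisting of a FASTA-style header line `>id`, one line holding the
#' amino-acid sequence, and then one whitespace-separated line per residue of
#' either `index score` or `index aa score`, with 1-based contiguous indices.
#' Sentinel scores (`>= 900`) mark residues without a valid experimental
#' score and populate the records' `valid_mask`.
#'
#' @param path path to an existing file.
#' @return A list of [protein_record()]s, one per protein, in file order.
#'   Duplicate ids, malformed lines, non-contiguous indices and
#'   sequence/score length mismatches raise errors naming the file, line and
#'   protein involved.
#' @seealso [write_chezod_file()], [read_chezod_two_file()]
#' @export
read_chezod_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  records <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!startsWith(lines[i], ">")) {
      stop(sprintf("%s:%d: expected '>' header, got '%s'", path, i, lines[i]))
    }
    id <- sub("^>\\s*", "", lines[i])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    if (is.na(id) || !nzchar(id)) stop(sprintf("%s:%d: empty protein id", path, i))
    if (id %in% names(records)) stop(sprintf("%s:%d: duplicate id '%s'", path, i, id))
    i <- i + 1L
    if (i > n || startsWith(lines[i], ">")) {
      stop(sprintf("%s:%d: missing sequence line for '%s'", path, i - 1L, id))
    }
    sequence <- gsub("\\s", "", lines[i])
    i <- i + 1L
    idxs <- numeric(0)
    scores <- numeric(0)
    while (i <= n && nzchar(lines[i]) && !startsWith(lines[i], ">")) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (!(length(tok) %in% c(2L, 3L))) {
        stop(sprintf("%s:%d: malformed residue line '%s'", path, i, lines[i]))
      }
      idx <- suppressWarnings(as.integer(tok[1L]))
      val <- suppressWarnings(as.numeric(tok[length(tok)]))
      if (is.na(idx) || is.na(val)) {
        stop(sprintf("%s:%d: malformed residue line '%s'", path, i, lines[i]))
      }
      idxs <- c(idxs, idx)
      scores <- c(scores, val)
      i <- i + 1L
    }
    if (length(idxs) && !identical(as.integer(idxs), seq_along(idxs))) {
      stop(sprintf("%s: protein '%s': residue indices not 1-based contiguous", path, id))
    }
    if (nchar(sequence) != length(scores)) {
      stop(sprintf("%s: protein '%s': sequence length %d != %d scores",
                   path, id, nchar(sequence), length(scores)))
    }
    records[[id]] <- protein_record(id, sequence, scores)
  }
  unname(records)
}

#' Write protein records in the canonical CheZOD dialect
#'
#' Scores are serialized with 17 significant digits so that
#' `read_chezod_file(write_chezod_file(x))` reproduces them bit-identically.
#'
#' @param records list of [protein_record()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chezod_file <- function(records, path) {
  if (inherits(records, "protein_record")) records <- list(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in records) {
    stopifnot(inherits(rec, "protein_record"))
    writeLines(paste0(">", rec$id), con)
    writeLines(rec$sequence, con)
    if (length(rec$scores)) {
      writeLines(sprintf("%d %.17g", seq_along(rec$scores), rec$scores), con)
    }
  }
  invisible(path)
}

#' Read the tolerant two-file form: FASTA plus per-protein score files
#'
#' Accepts a FASTA file of sequences and a directory containing one plain
#' score file per protein named `<id>.txt` (or `<id>` bare), each holding one
#' score per line, or `index score` pairs.
#'
#' @param fasta_path FASTA file of amino-acid sequences.
#' @param score_dir directory of per-protein score files.
#' @return A list of [protein_record()]s in FASTA order.
#' @export
read_chezod_two_file <- function(fasta_path, score_dir) {
  seqs <- read_fasta(fasta_path)
  lapply(names(seqs), function(id) {
    cand <- file.path(score_dir, c(paste0(id, ".txt"), id))
    sf <- cand[file.exists(cand)][1L]
    if (is.na(sf)) stop(sprintf("no score file for protein '%s' in %s", id, score_dir))
    tok <- scan(sf, what = numeric(), quiet = TRUE)
    fields <- length(strsplit(trimws(readLines(sf, n = 1L)), "\\s+")[[1L]])
    scores <- if (fields >= 2L) matrix(tok, ncol = fields, byrow = TRUE)[, fields] else tok
    protein_record(id, seqs[[id]], scores)
  })
}

#' Read an amino-acid FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (first whitespace-delimited
#'   header token is the name).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or list of [protein_record()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1L]], "protein_record")) {
    nm <- vapply(seqs, `[[`, "", "id")
    seqs <- stats::setNames(vapply(seqs, `[[`, "", "sequence"), nm)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}
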