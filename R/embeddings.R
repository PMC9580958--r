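#' Write per-protein embedding matrices to an HDF5 container
#'
#' One float dataset per protein, keyed by protein id, plus a root attribute
#' `dim` recording the shared embedding dimension N. Matrices are stored
#' residues x dimensions (L x N).
#'
#' @param embeddings named list of L x N numeric matrices (names = ids).
#' @param path output `.h5` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(is.list(embeddings), length(embeddings) > 0L,
            !is.null(names(embeddings)), all(nzchar(names(embeddings))))
  dims <- vapply(embeddings, ncol, 0L)
  if (length(unique(dims)) != 1L) {
    stop("all embedding matrices must share one dimension N")
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (id in names(embeddings)) {
    m <- unclass(embeddings[[id]])
    attr(m, "protein_id") <- NULL
    rhdf5::h5write(m, path, id)
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.integer(dims[1L]), fid, "dim")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an HDF5 embedding container
#'
#' @param path container written by [write_embeddings()] (or any HDF5 file
#'   with one L x N float dataset per protein at the root).
#' @param ids optional character vector restricting which proteins to load;
#'   a missing id raises an error.
#' @return Named list of [embedding_matrix()] objects. An inconsistent
#'   dimension N across proteins raises an error.
#' @export
read_embeddings <- function(path, ids = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  info <- rhdf5::h5ls(path, recursive = FALSE)
  all_ids <- info$name[info$otype == "H5I_DATASET"]
  if (is.null(ids)) {
    ids <- all_ids
  } else {
    missing <- setdiff(ids, all_ids)
    if (length(missing)) {
      stop(sprintf("protein id(s) not in container %s: %s",
                   path, paste(missing, collapse = ", ")))
    }
  }
  out <- lapply(ids, function(id) {
    m <- rhdf5::h5read(path, id)
    embedding_matrix(as.matrix(m), protein_id = id)
  })
  names(out) <- ids
  rhdf5::h5closeAll()
  dims <- vapply(out, ncol, 0L)
  if (length(unique(dims)) > 1L) {
    stop(sprintf("inconsistent embedding dimensions in %s: %s",
                 path, paste(sort(unique(dims)), collapse = " vs ")))
  }
  out
}
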