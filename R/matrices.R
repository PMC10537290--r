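#' Validate a binary drug--side-effect association matrix
#'
#' Checks that `values` is a numeric matrix containing only 0/1 entries and
#' attaches row (drug) and column (side-effect) identifiers. The association
#' matrix is the label source of the whole method and also supplies half of
#' every node attribute vector, so it is validated strictly: anything that is
#' not exactly 0 or 1 is rejected, never coerced.
#'
#' @param values Numeric matrix, drugs in rows, side-effects in columns.
#' @param drug_ids,side_effect_ids Optional character identifiers; default to
#'   existing dimnames or generated `drug_*` / `se_*` labels. Must be unique
#'   and match the matrix dimensions.
#' @return The matrix with dimnames set (invisibly classed input is not used;
#'   plain matrices flow through the package).
#' @export
association_matrix <- function(values, drug_ids = NULL, side_effect_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("association matrix must be a numeric matrix")
  if (!all(values %in% c(0, 1)))
    stopf("association matrix has entries outside {0,1}")
  drug_ids <- drug_ids %||% rownames(values) %||%
    sprintf("drug_%03d", seq_len(nrow(values)))
  side_effect_ids <- side_effect_ids %||% colnames(values) %||%
    sprintf("se_%03d", seq_len(ncol(values)))
  if (length(drug_ids) != nrow(values))
    stopf("drug_ids length %d != %d rows", length(drug_ids), nrow(values))
  if (length(side_effect_ids) != ncol(values))
    stopf("side_effect_ids length %d != %d columns",
          length(side_effect_ids), ncol(values))
  if (anyDuplicated(drug_ids) || anyDuplicated(side_effect_ids))
    stopf("node identifiers must be unique")
  dimnames(values) <- list(drug_ids, side_effect_ids)
  values
}

#' Validate a similarity matrix
#'
#' A similarity matrix must be square, symmetric (within `tol`), have a unit
#' diagonal, and entries in \[0,1\]. Malformed inputs are rejected, not
#' clipped: silently repairing a similarity matrix would mask upstream
#' preprocessing errors.
#'
#' @param values Numeric square matrix.
#' @param ids Optional node identifiers (default dimnames or generated).
#' @param modality Optional tag, e.g. `"che"` or `"dis"` for the two drug
#'   similarity modalities; stored as the `"modality"` attribute.
#' @param tol Numeric tolerance for the symmetry and diagonal checks.
#' @return The validated matrix with dimnames and modality attribute.
#' @export
similarity_matrix <- function(values, ids = NULL, modality = NULL, tol = 1e-8) {
  if (!is.matrix(values) || !is.numeric(values) || nrow(values) != ncol(values))
    stopf("similarity matrix must be a square numeric matrix")
  if (any(values < -tol) || any(values > 1 + tol))
    stopf("similarity matrix has entries outside [0,1] (min %.4g, max %.4g)",
          min(values), max(values))
  if (max(abs(values - t(values))) > tol)
    stopf("similarity matrix is not symmetric (max asymmetry %.4g)",
          max(abs(values - t(values))))
  if (max(abs(diag(values) - 1)) > tol)
    stopf("similarity matrix diagonal is not 1")
  ids <- ids %||% rownames(values) %||% sprintf("node_%03d", seq_len(nrow(values)))
  if (length(ids) != nrow(values) || anyDuplicated(ids))
    stopf("ids must be unique and match the matrix dimension")
  dimnames(values) <- list(ids, ids)
  attr(values, "modality") <- modality
  values
}

#' Cosine similarity between the rows of a profile matrix
#'
#' Standard cosine similarity over (typically binary) row profiles, used to
#' derive drug chemical-substructure similarities from fingerprints and as
#' the fallback builder for the side-effect similarity (cosine over the
#' association matrix columns). For non-negative profiles the result is a
#' valid similarity matrix: symmetric, unit diagonal, entries in \[0,1\].
#'
#' All-zero rows have no direction; their off-diagonal similarities are
#' defined as 0 (diagonal 1) and a warning is emitted.
#'
#' @param profiles Numeric matrix, one entity per row.
#' @param ids Optional row identifiers.
#' @param modality Optional modality tag passed to [similarity_matrix()].
#' @return Validated similarity matrix (rows x rows).
#' @export
cosine_profile_similarity <- function(profiles, ids = NULL, modality = NULL) {
  if (!is.matrix(profiles) || !is.numeric(profiles))
    stopf("profiles must be a numeric matrix")
  nrm <- sqrt(rowSums(profiles^2))
  zero <- nrm == 0
  if (any(zero)) {
    warnf("%d all-zero profile row(s); their similarities are set to 0",
          sum(zero))
    nrm[zero] <- 1 # rows are all-zero, so the product below is already 0
  }
  sim <- tcrossprod(profiles / nrm)
  diag(sim) <- 1
  sim[sim < 0] <- 0
  sim[sim > 1] <- 1
  similarity_matrix(sim, ids = ids %||% rownames(profiles), modality = modality)
}

#' Read / write a delimited matrix with identifier header row and column
#'
#' Plain-text exchange format for the association and similarity matrices:
#' tab-separated values with column identifiers in the header and row
#' identifiers in the first column. Round-trips are lossless for binary
#' matrices and preserve at least 12 significant digits for similarities.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return `read_matrix_tsv()` returns a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, row.names = 1L, sep = sep,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param m Numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path, sep = "\t") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("row_%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("col_%03d", seq_len(ncol(m)))
  out <- cbind(id = rownames(m), as.data.frame(signif(m, 15)))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cache an R object to disk (runtime cache, RDS container)
#'
#' Convenience wrappers for caching assembled adjacency matrices, attribute
#' blocks, or trained parameter checkpoints between pipeline stages.
#'
#' @param object Any R object.
#' @param path File path (conventionally `.rds`).
#' @export
save_cache <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_cache
#' @export
load_cache <- function(path) {
  if (!file.exists(path)) stopf("cache file not found: %s", path)
  readRDS(path)
}
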