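#' Same-type neighbor extraction
#'
#' Returns the indices of the `nt` nodes of the same type most similar to
#' node `i` according to its similarity row, the target itself included.
#' The target is listed first (it is its own most similar neighbor, the
#' diagonal being 1); the remaining slots are filled by descending
#' similarity, ties broken by ascending index so the result is
#' deterministic.
#'
#' @param sim Similarity matrix over nodes of one type.
#' @param i Target index.
#' @param nt Neighborhood size (>= 1), target included.
#' @return Integer vector of length `min(nt, nrow(sim))`, starting with `i`.
#' @export
same_type_neighbors <- function(sim, i, nt) {
  if (!is_count(nt)) stopf("nt must be a positive integer")
  n <- nrow(sim)
  if (!is_count(i) || i > n) stopf("index %s out of range [1, %d]", format(i), n)
  if (nt == 1L) return(i)
  others <- setdiff(seq_len(n), i)
  ord <- others[order(-sim[i, others], others)]
  c(i, utils::head(ord, nt - 1L))
}

#' Cross-type neighbor extraction
#'
#' Returns the indices of the other-type nodes associated with the target:
#' for a drug, the side-effects with a 1 in its association row; for a
#' side-effect, the drugs with a 1 in its association column. Indices are in
#' ascending order and truncated to the first `nk`; the list may be empty.
#'
#' @param A Binary association matrix (drugs x side-effects).
#' @param i Target index (drug row or side-effect column, per `type`).
#' @param nk Maximum number of neighbors (>= 0).
#' @param type `"drug"` (use row `i` of `A`) or `"side_effect"` (column `i`).
#' @return Integer vector (possibly empty) of other-type indices.
#' @export
cross_type_neighbors <- function(A, i, nk, type = c("drug", "side_effect")) {
  type <- match.arg(type)
  if (!is.numeric(nk) || length(nk) != 1L || nk < 0 || nk != floor(nk))
    stopf("nk must be a non-negative integer")
  hits <- if (type == "drug") which(A[i, ] == 1) else which(A[, i] == 1)
  utils::head(as.integer(hits), nk)
}

#' Precompute neighbor sets for every node of a heterogeneous graph
#'
#' For each of the `N_total` nodes, extracts the same-type neighbor list
#' (top-`nt` by similarity, self first) and the cross-type neighbor list
#' (associated nodes, ascending, truncated to `nk`). Cross-type indices are
#' returned in global node numbering (side-effect `j` is node `nr + j`).
#' Nodes with no associations simply get an empty cross-type list; the
#' encoder then drops that neighbor category for them.
#'
#' @param graph A `hetero_graph`.
#' @param nt,nk Same-type / cross-type neighborhood sizes.
#' @return List with elements `same` and `cross`, each a list of length
#'   `N_total` of global node index vectors.
#' @export
build_neighbor_sets <- function(graph, nt, nk) {
  nr <- graph$nr; ns <- graph$ns
  Dsim <- graph$adjacency[seq_len(nr), seq_len(nr), drop = FALSE]
  Ssim <- graph$adjacency[nr + seq_len(ns), nr + seq_len(ns), drop = FALSE]
  A <- graph$adjacency[seq_len(nr), nr + seq_len(ns), drop = FALSE]
  same <- vector("list", graph$n_total)
  cross <- vector("list", graph$n_total)
  for (i in seq_len(nr)) {
    same[[i]] <- same_type_neighbors(Dsim, i, nt)
    cross[[i]] <- nr + cross_type_neighbors(A, i, nk, "drug")
  }
  for (j in seq_len(ns)) {
    same[[nr + j]] <- nr + same_type_neighbors(Ssim, j, nt)
    cross[[nr + j]] <- cross_type_neighbors(A, j, nk, "side_effect")
  }
  list(same = same, cross = cross)
}
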