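#' Build a drug--side-effect heterogeneous graph
#'
#' Assembles the block adjacency matrix
#' \deqn{I = \begin{bmatrix} D & A \\ A^T & S \end{bmatrix}}
#' of one heterogeneous graph from a drug--drug similarity matrix `D`
#' (one modality: chemical-substructure or disease-based), the binary
#' drug--side-effect association matrix `A`, and the side-effect similarity
#' matrix `S`. Node ordering is fixed: drugs occupy rows/columns `1..Nr`,
#' side-effects `Nr+1..Nr+Ns`. Row `v` of the adjacency is the raw attribute
#' vector of node `v`: for a drug it concatenates its similarities with all
#' drugs and its associations with all side-effects, and symmetrically for a
#' side-effect.
#'
#' @param D Drug similarity matrix (`Nr x Nr`), see [similarity_matrix()].
#' @param A Binary association matrix (`Nr x Ns`), see [association_matrix()].
#' @param S Side-effect similarity matrix (`Ns x Ns`).
#' @param modality Optional modality tag (defaults to `D`'s modality).
#' @return An object of class `hetero_graph`: a list with `adjacency`
#'   (`N_total x N_total`), `nr`, `ns`, `n_total`, `modality`, `drug_ids`,
#'   `side_effect_ids`.
#' @export
build_adjacency <- function(D, A, S, modality = NULL) {
  A <- association_matrix(A)
  nr <- nrow(A); ns <- ncol(A)
  if (nrow(D) != nr || ncol(D) != nr)
    stopf("drug similarity matrix D is %dx%d but A has %d drug rows",
          nrow(D), ncol(D), nr)
  if (nrow(S) != ns || ncol(S) != ns)
    stopf("side-effect similarity matrix S is %dx%d but A has %d side-effect columns",
          nrow(S), ncol(S), ns)
  D <- similarity_matrix(unclass(D), ids = rownames(A),
                         modality = modality %||% attr(D, "modality"))
  S <- similarity_matrix(unclass(S), ids = colnames(A))
  adj <- rbind(cbind(D, A), cbind(t(A), S))
  ids <- c(rownames(A), colnames(A))
  dimnames(adj) <- list(ids, ids)
  structure(list(adjacency = adj, nr = nr, ns = ns, n_total = nr + ns,
                 modality = attr(D, "modality"),
                 drug_ids = rownames(A), side_effect_ids = colnames(A)),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("heterogeneous drug-side-effect graph%s: %d drugs + %d side-effects = %d nodes\n",
              if (is.null(x$modality)) "" else sprintf(" [%s]", x$modality),
              x$nr, x$ns, x$n_total))
  invisible(x)
}

check_drug_index <- function(graph, i) {
  if (!is_count(i) || i > graph$nr)
    stopf("drug index %s out of range [1, %d]", format(i), graph$nr)
}

check_side_effect_index <- function(graph, j) {
  if (!is_count(j) || j > graph$ns)
    stopf("side-effect index %s out of range [1, %d]", format(j), graph$ns)
}

#' Raw node attribute vectors
#'
#' The attribute vector of drug `i` concatenates row `i` of the drug
#' similarity matrix with row `i` of the association matrix; that of
#' side-effect `j` concatenates column `j` of the association matrix with
#' column `j` of the side-effect similarity matrix. Both equal the
#' corresponding row of the assembled adjacency (drug `i` is node `i`,
#' side-effect `j` is node `Nr + j`); the side-effect vector does not depend
#' on the drug-similarity modality.
#'
#' @param graph A `hetero_graph` from [build_adjacency()].
#' @param i Drug index in `1..Nr`.
#' @return Numeric vector of length `N_total`.
#' @export
drug_attribute_vector <- function(graph, i) {
  check_drug_index(graph, i)
  graph$adjacency[i, ]
}

#' @rdname drug_attribute_vector
#' @param j Side-effect index in `1..Ns`.
#' @export
side_effect_attribute_vector <- function(graph, j) {
  check_side_effect_index(graph, j)
  graph$adjacency[graph$nr + j, ]
}

#' Pair embedding of a drug--side-effect node pair
#'
#' Stacks the drug attribute vector on the side-effect attribute vector into
#' a `2 x N_total` matrix -- the raw pairwise feature map of one graph.
#'
#' @inheritParams drug_attribute_vector
#' @param j Side-effect index.
#' @return `2 x N_total` numeric matrix (row 1 drug, row 2 side-effect).
#' @export
pair_embedding <- function(graph, i, j) {
  rbind(drug_attribute_vector(graph, i), side_effect_attribute_vector(graph, j))
}

#' Stacked two-graph pair embedding
#'
#' Stacks the pair embeddings from the chemical-substructure graph and the
#' disease-based graph into the `4 x N_total` single-channel map consumed by
#' the capsule scorer (rows: drug/che, side-effect, drug/dis, side-effect).
#'
#' @param graph_che,graph_dis The two `hetero_graph`s (must share `A` and `S`).
#' @param i,j Drug and side-effect indices.
#' @return `4 x N_total` numeric matrix.
#' @export
stacked_pair_embedding <- function(graph_che, graph_dis, i, j) {
  if (graph_che$n_total != graph_dis$n_total || graph_che$nr != graph_dis$nr)
    stopf("the two graphs have inconsistent dimensions")
  rbind(pair_embedding(graph_che, i, j), pair_embedding(graph_dis, i, j))
}
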