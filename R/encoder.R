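## Context encoder: a multi-layer, multi-head graph transformer over typed
## neighbor sets. Each node attends separately to its same-type neighbors
## (drug-drug or side-effect-side-effect similarity edges) and to its
## cross-type neighbors (association edges); an edge-semantic matrix W_d per
## neighbor category injects the connection semantics into the attention
## score. Category-level attention fuses the two neighbor encodings, a
## residual projection re-injects the raw attribute vector, and a 1x1
## convolution (two scalar weights + bias shared across features) fuses the
## two heterogeneous graphs.

#' Initialize context-encoder parameters
#'
#' Glorot-style uniform initialization of all encoder parameters for both
#' heterogeneous graphs: per layer and graph the stacked per-head
#' query/key/value maps, three edge-semantic matrices per head (drug
#' similarity, side-effect similarity, association), and the
#' category-attention bottleneck; plus the per-graph residual projection,
#' graph-fusion weights, and the final pair classifier.
#'
#' @param n_total Number of graph nodes (input attribute dimension).
#' @param config An [adverank_config()].
#' @param seed Optional seed for reproducible initialization.
#' @return Nested parameter list (`graphs$che`, `graphs$dis`, `fusion`,
#'   `classifier`).
#' @export
init_context_encoder <- function(n_total, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  init_layer <- function(d_prev, d_out, heads, att_dim) {
    n <- d_out %/% heads
    wd1 <- function() {
      a <- array(0, dim = c(n, n, heads))
      for (t in seq_len(heads)) a[, , t] <- glorot(n, n)
      a
    }
    list(Wq = glorot(d_out, d_prev),
         Wk = glorot(d_out, d_prev),
         Wv = glorot(d_out, d_prev),
         Wd = list(rr = wd1(), ss = wd1(), ra = wd1()),
         att = list(W = glorot(att_dim, d_out),
                    b = numeric(att_dim),
                    h = as.vector(glorot(att_dim, 1))))
  }
  init_graph <- function() {
    d <- c(n_total, config$dims)
    layers <- lapply(seq_len(config$layers), function(l)
      init_layer(d[l], d[l + 1L], config$heads, config$att_dim))
    list(layers = layers,
         res = glorot(config$dims[config$layers], n_total))
  }
  m_fin <- config$dims[config$layers]
  list(graphs = list(che = init_graph(), dis = init_graph()),
       fusion = list(w = c(0.5, 0.5), b = 0),
       classifier = list(W = glorot(2L, 2L * m_fin), b = numeric(2L)))
}

## ---- unit operations (the algebra of one attention step) -------------------

#' Per-head query projection
#'
#' Linear map of a node's previous-layer state by the head's query matrix;
#' at layer 1 the state is the raw attribute vector.
#'
#' @param W_q Query weight matrix (`n x d_prev`).
#' @param state Previous-layer state vector (`d_prev`).
#' @return Query vector of length `n`.
#' @export
head_query <- function(W_q, state) {
  if (ncol(W_q) != length(state))
    stopf("query weight matrix is %dx%d but the state has length %d",
          nrow(W_q), ncol(W_q), length(state))
  as.vector(W_q %*% state)
}

#' Per-head key and value matrices over a neighbor member list
#'
#' Applies the key (value) weight matrix to each member's previous-layer
#' state; row order equals input order, target first then neighbors.
#'
#' @param W_k,W_v Key/value weight matrices (`n x d_prev`).
#' @param states Member states, one row per member (target first).
#' @return List with `K` and `V`, each `|members| x n`.
#' @export
head_keys_values <- function(W_k, W_v, states) {
  if (!is.matrix(states) || nrow(states) == 0L)
    stopf("member state matrix must be non-empty")
  list(K = states %*% t(W_k), V = states %*% t(W_v))
}

#' Edge-semantic attention scores
#'
#' Bilinear attention score of each member against the target query through
#' the neighbor-category-specific semantic matrix: `score_m = K_m' W_d q`.
#' The method defines no `1/sqrt(n)` scaling; `scaled = TRUE` enables the
#' conventional variant.
#'
#' @param K Key matrix (`M x n`).
#' @param q Query vector (`n`).
#' @param W_d Edge-semantic matrix (`n x n`) for the member category.
#' @param scaled Apply `1/sqrt(n)` scaling (default `FALSE`).
#' @return Numeric score vector of length `M`.
#' @export
semantic_attention_scores <- function(K, q, W_d, scaled = FALSE) {
  n <- length(q)
  if (!all(dim(W_d) == c(n, n)) || ncol(K) != n)
    stopf("shape mismatch: K is %dx%d, W_d is %dx%d, q has length %d",
          nrow(K), ncol(K), nrow(W_d), ncol(W_d), n)
  s <- as.vector(K %*% (W_d %*% q))
  if (scaled) s / sqrt(n) else s
}

#' Softmax-normalize scores and aggregate value rows
#'
#' Numerically stabilized softmax over the member scores followed by the
#' weighted sum of value rows: one head's neighbor-context vector.
#'
#' @param scores Score vector over members.
#' @param V Value matrix (`M x n`).
#' @return List with `weights` (sum to 1) and `context` (length `n`).
#' @export
normalize_and_aggregate <- function(scores, V) {
  if (length(scores) == 0L) stopf("at least one member is required")
  g <- softmax(scores)
  list(weights = g, context = as.vector(crossprod(V, g)))
}

#' Concatenate per-head context vectors
#'
#' @param head_outputs List of `T` vectors of equal length `n`.
#' @return Vector of length `n * T`, head order preserved.
#' @export
concat_heads <- function(head_outputs) {
  if (length(head_outputs) == 0L || any(vapply(head_outputs, is.null, TRUE)))
    stopf("all head outputs must be present")
  len <- lengths(head_outputs)
  if (length(unique(len)) != 1L) stopf("head outputs differ in length")
  unlist(head_outputs, use.names = FALSE)
}

#' Neighbor-category attention
#'
#' Scores each available neighbor-category encoding through a shared tanh
#' bottleneck (`s_u = h' tanh(W y_u + b)`), softmax-normalizes the scores
#' into category weights `beta` (summing to 1), and returns the
#' beta-weighted combination. A node with no cross-type neighbors has a
#' single category, which then receives weight 1.
#'
#' @param y_list Named list of category encodings (1 or 2 vectors of equal
#'   length).
#' @param att List with `W`, `b`, `h` (the attention bottleneck parameters).
#' @return List with `output`, `beta`, and the per-category scores `s`.
#' @export
category_attention <- function(y_list, att) {
  if (length(y_list) == 0L) stopf("at least one category encoding is required")
  a_list <- lapply(y_list, function(y) tanh(as.vector(att$W %*% y) + att$b))
  s <- vapply(a_list, function(a) sum(att$h * a), numeric(1))
  beta <- softmax(s)
  out <- Reduce(`+`, Map(`*`, y_list, as.list(beta)))
  list(output = out, beta = beta, s = s, a_list = a_list)
}

#' Residual projection of the raw attribute vector
#'
#' Adds a learned linear map of the relu-activated raw attribute vector to
#' the final-layer encoding (attributes are similarities/associations in
#' \[0,1\], so relu is the identity on well-formed inputs; it guards
#' malformed ones).
#'
#' @param W_res Projection matrix (`n_fin x N_total`).
#' @param x_raw Raw attribute vector (`N_total`).
#' @param z_last Final-layer encoding (`n_fin`).
#' @return Vector of length `n_fin`.
#' @export
residual_projection <- function(W_res, x_raw, z_last) {
  as.vector(W_res %*% relu(x_raw)) + z_last
}

#' Graph-level fusion (two-channel 1x1 convolution)
#'
#' Per-feature combination `w_che * z_che + w_dis * z_dis + bias` with the
#' two scalar weights and the scalar bias shared across features -- a 1x1
#' convolution over the two graph channels, realizing the graph-level
#' attention.
#'
#' @param z_che,z_dis Encodings from the two graphs (vectors or matrices of
#'   identical shape).
#' @param w Length-2 weight vector `(w_che, w_dis)`.
#' @param b Scalar bias.
#' @return Fused encoding, same shape as the inputs.
#' @export
graph_fusion <- function(z_che, z_dis, w, b = 0) {
  if (length(w) != 2L) stopf("fusion weight vector must have length 2")
  w[1L] * z_che + w[2L] * z_dis + b
}

#' Encoder association probability for a pair feature
#'
#' Softmax classifier over the concatenated fused encodings of the drug and
#' the side-effect node. Component 2 is the association probability.
#'
#' @param classifier List with `W` (`2 x 2 n_fin`) and `b` (length 2).
#' @param z_i,z_j Fused node encodings.
#' @return Probability pair `(not associated, associated)` summing to 1.
#' @export
encoder_score <- function(classifier, z_i, z_j) {
  softmax(as.vector(classifier$W %*% c(z_i, z_j)) + classifier$b)
}

## ---- full forward pass -----------------------------------------------------

## 0/1 block-selection matrix mapping the (head, head-dim) flat layout onto
## per-head columns; column t selects entries of head t.
head_blockmat <- function(n, heads) kronecker(diag(heads), rep(1, n))

edge_class_same <- function(v, nr) if (v <= nr) "rr" else "ss"

## Forward pass of one graph's encoder stack. Returns per-layer states
## (states[[1]] are the raw attributes), the post-residual encoding z_add,
## and, when keep_cache, the per-node attention caches for backprop.
forward_graph <- function(gp, X, nbr, nr, config, keep_cache = FALSE) {
  N <- nrow(X)
  Tt <- config$heads
  states <- vector("list", config$layers + 1L)
  states[[1L]] <- X
  caches <- if (keep_cache) vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    lp <- gp$layers[[l]]
    Tn <- config$dims[l]
    n <- Tn %/% Tt
    bm <- head_blockmat(n, Tt)
    hrep <- rep(seq_len(Tt), each = n)
    prev <- states[[l]]
    out <- matrix(0, N, Tn)
    cache_l <- if (keep_cache) vector("list", N)
    for (v in seq_len(N)) {
      q_all <- as.vector(lp$Wq %*% prev[v, ])
      cats <- list(same = list(members = nbr$same[[v]],
                               e = edge_class_same(v, nr)))
      if (length(nbr$cross[[v]]) > 0L)
        cats$cross <- list(members = c(v, nbr$cross[[v]]), e = "ra")
      y_list <- vector("list", length(cats))
      names(y_list) <- names(cats)
      for (u in names(cats)) {
        members <- cats[[u]]$members
        C <- prev[members, , drop = FALSE]
        K <- tcrossprod(C, lp$Wk)
        V <- tcrossprod(C, lp$Wv)
        Wd <- lp$Wd[[cats[[u]]$e]]
        Wdq <- numeric(Tn)
        for (t in seq_len(Tt)) {
          idx <- ((t - 1L) * n + 1L):(t * n)
          Wdq[idx] <- Wd[, , t] %*% q_all[idx]
        }
        if (config$scaled_attention) Wdq <- Wdq / sqrt(n)
        alpha <- K %*% (bm * Wdq)
        gamma <- softmax_cols(alpha)
        y <- as.vector(colSums(V * gamma[, hrep, drop = FALSE]))
        y_list[[u]] <- y
        if (keep_cache)
          cats[[u]][c("K", "V", "gamma", "Wdq", "y")] <-
            list(K, V, gamma, Wdq, y)
      }
      ca <- category_attention(y_list, lp$att)
      out[v, ] <- ca$output
      if (keep_cache)
        cache_l[[v]] <- list(q_all = q_all, cats = cats, beta = ca$beta,
                             a_list = ca$a_list, y_list = y_list)
    }
    states[[l + 1L]] <- out
    if (keep_cache) caches[[l]] <- cache_l
  }
  z_add <- relu(X) %*% t(gp$res) + states[[config$layers + 1L]]
  list(states = states, z_add = z_add, caches = caches)
}

#' Full context-encoder forward pass
#'
#' Encodes every node of both heterogeneous graphs through the layered
#' attention stack, applies the residual attribute projection per graph, and
#' fuses the two graph encodings into the final per-node contextual
#' representation.
#'
#' @param params Parameters from [init_context_encoder()].
#' @param graphs List with `che` and `dis` [build_adjacency()] graphs.
#' @param nbrs List with per-graph neighbor sets from
#'   [build_neighbor_sets()] (`nbrs$che`, `nbrs$dis`).
#' @param config An [adverank_config()].
#' @param keep_cache Keep attention caches (needed for backprop).
#' @return List with `z_fin` (`N_total x n_fin`), per-graph `z_add` and
#'   layer `states`, and caches when requested.
#' @export
context_encoder_forward <- function(params, graphs, nbrs, config,
                                    keep_cache = FALSE) {
  nr <- graphs$che$nr
  fche <- forward_graph(params$graphs$che, graphs$che$adjacency, nbrs$che,
                        nr, config, keep_cache)
  fdis <- forward_graph(params$graphs$dis, graphs$dis$adjacency, nbrs$dis,
                        nr, config, keep_cache)
  z_fin <- graph_fusion(fche$z_add, fdis$z_add,
                        params$fusion$w, params$fusion$b)
  list(z_fin = z_fin, che = fche, dis = fdis)
}

#' Encoder association probabilities for a set of pairs
#'
#' @param params Encoder parameters.
#' @param fwd Output of [context_encoder_forward()].
#' @param nr Number of drugs (side-effect `j` is node `nr + j`).
#' @param pairs Two-column matrix of (drug index, side-effect index).
#' @return `nrow(pairs) x 2` matrix of probabilities; column 2 is the
#'   association probability.
#' @export
encoder_pair_scores <- function(params, fwd, nr, pairs) {
  z <- fwd$z_fin
  Zp <- cbind(z[pairs[, 1L], , drop = FALSE],
              z[nr + pairs[, 2L], , drop = FALSE])
  logits <- Zp %*% t(params$classifier$W) +
    matrix(params$classifier$b, nrow(Zp), 2L, byrow = TRUE)
  softmax_rows(logits)
}
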