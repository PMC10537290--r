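## Analytic backpropagation for the context encoder. The backward pass
## mirrors forward_graph() exactly: classifier -> graph fusion -> residual
## projection -> layered attention, with gradients accumulated over all
## nodes and layers of the whole graph (the encoder is transductive, so a
## layer-l state feeds every node that lists it as a neighbor at layer l+1).
## Correctness is pinned by finite-difference checks in the test suite.

backward_graph <- function(gp, X, nbr, nr, config, fg, dz_add) {
  g <- zeros_like(gp)
  g$res <- crossprod(dz_add, relu(X))
  dstates <- dz_add
  Tt <- config$heads
  for (l in rev(seq_len(config$layers))) {
    lp <- gp$layers[[l]]
    cache_l <- fg$caches[[l]]
    prev <- fg$states[[l]]
    Tn <- config$dims[l]
    n <- Tn %/% Tt
    bm <- head_blockmat(n, Tt)
    hrep <- rep(seq_len(Tt), each = n)
    N <- nrow(prev)
    dprev <- matrix(0, N, ncol(prev))
    gWq <- gWk <- gWv <- matrix(0, Tn, ncol(prev))
    gWd <- lapply(lp$Wd, function(a) a * 0)
    gattW <- lp$att$W * 0; gattb <- lp$att$b * 0; gatth <- lp$att$h * 0
    for (v in seq_len(N)) {
      dZcon <- dstates[v, ]
      ch <- cache_l[[v]]
      beta <- ch$beta
      dbeta <- vapply(ch$y_list, function(y) sum(dZcon * y), numeric(1))
      ds <- beta * (dbeta - sum(beta * dbeta))
      dq_all <- numeric(Tn)
      for (u in names(ch$cats)) {
        cat_u <- ch$cats[[u]]
        yu <- ch$y_list[[u]]
        au <- ch$a_list[[u]]
        dy <- beta[[u]] * dZcon
        ## category-attention bottleneck
        dpre <- (ds[[u]] * lp$att$h) * (1 - au^2)
        gattW <- gattW + outer(dpre, yu)
        gattb <- gattb + dpre
        gatth <- gatth + ds[[u]] * au
        dy <- dy + as.vector(crossprod(lp$att$W, dpre))
        ## multi-head neighbor attention
        M <- length(cat_u$members)
        gamma <- cat_u$gamma
        dymat <- matrix(dy, M, Tn, byrow = TRUE)
        gexp <- gamma[, hrep, drop = FALSE]
        dV <- gexp * dymat
        dgam <- (cat_u$V * dymat) %*% bm
        dalpha <- gamma * (dgam - matrix(colSums(gamma * dgam), M, Tt,
                                         byrow = TRUE))
        dalpha_exp <- dalpha[, hrep, drop = FALSE]
        dK <- dalpha_exp * matrix(cat_u$Wdq, M, Tn, byrow = TRUE)
        dWdq <- colSums(cat_u$K * dalpha_exp)
        if (config$scaled_attention) dWdq <- dWdq / sqrt(n)
        Wd <- lp$Wd[[cat_u$e]]
        for (t in seq_len(Tt)) {
          idx <- ((t - 1L) * n + 1L):(t * n)
          gWd[[cat_u$e]][, , t] <- gWd[[cat_u$e]][, , t] +
            outer(dWdq[idx], ch$q_all[idx])
          dq_all[idx] <- dq_all[idx] + as.vector(crossprod(Wd[, , t], dWdq[idx]))
        }
        C <- prev[cat_u$members, , drop = FALSE]
        dC <- dK %*% lp$Wk + dV %*% lp$Wv
        gWk <- gWk + crossprod(dK, C)
        gWv <- gWv + crossprod(dV, C)
        for (k in seq_len(M))
          dprev[cat_u$members[k], ] <- dprev[cat_u$members[k], ] + dC[k, ]
      }
      gWq <- gWq + outer(dq_all, prev[v, ])
      dprev[v, ] <- dprev[v, ] + as.vector(crossprod(lp$Wq, dq_all))
    }
    g$layers[[l]]$Wq <- gWq
    g$layers[[l]]$Wk <- gWk
    g$layers[[l]]$Wv <- gWv
    g$layers[[l]]$Wd <- gWd
    g$layers[[l]]$att <- list(W = gattW, b = gattb, h = gatth)
    dstates <- dprev
  }
  g
}

## Summed cross-entropy loss over a pair batch plus gradients for every
## encoder parameter.
encoder_loss_grads <- function(params, graphs, nbrs, config, pairs, labels) {
  nr <- graphs$che$nr
  fwd <- context_encoder_forward(params, graphs, nbrs, config,
                                 keep_cache = TRUE)
  z <- fwd$z_fin
  m <- ncol(z)
  Zp <- cbind(z[pairs[, 1L], , drop = FALSE],
              z[nr + pairs[, 2L], , drop = FALSE])
  logits <- Zp %*% t(params$classifier$W) +
    matrix(params$classifier$b, nrow(Zp), 2L, byrow = TRUE)
  probs <- softmax_rows(logits)
  Y <- cbind(1 - labels, labels)
  loss <- cross_entropy_loss(probs, labels)
  dlogits <- probs - Y
  grads <- zeros_like(params)
  grads$classifier$W <- crossprod(dlogits, Zp)
  grads$classifier$b <- colSums(dlogits)
  dZp <- dlogits %*% params$classifier$W
  contrib <- rbind(dZp[, seq_len(m), drop = FALSE],
                   dZp[, m + seq_len(m), drop = FALSE])
  idx <- c(pairs[, 1L], nr + pairs[, 2L])
  agg <- rowsum(contrib, idx)
  dz_fin <- matrix(0, nrow(z), m)
  dz_fin[as.integer(rownames(agg)), ] <- agg
  grads$fusion$w <- c(sum(dz_fin * fwd$che$z_add),
                      sum(dz_fin * fwd$dis$z_add))
  grads$fusion$b <- sum(dz_fin)
  grads$graphs$che <- backward_graph(params$graphs$che, graphs$che$adjacency,
                                     nbrs$che, nr, config, fwd$che,
                                     params$fusion$w[1L] * dz_fin)
  grads$graphs$dis <- backward_graph(params$graphs$dis, graphs$dis$adjacency,
                                     nbrs$dis, nr, config, fwd$dis,
                                     params$fusion$w[2L] * dz_fin)
  list(loss = loss, grads = grads, probs = probs)
}

#' Train the context encoder
#'
#' Optimizes the encoder's summed cross-entropy loss over labeled
#' drug--side-effect pairs with Adam. The encoder is transductive: every
#' update re-encodes all nodes, so `encoder_batch_size = Inf` (full batch,
#' the default) is the economical regime; smaller batches are supported.
#' Training is deterministic given `seed`.
#'
#' @param graphs List with the `che` and `dis` [build_adjacency()] graphs
#'   (built from the *training* association matrix).
#' @param pairs Two-column matrix of (drug, side-effect) indices.
#' @param labels 0/1 vector, one per pair.
#' @param config An [adverank_config()].
#' @param params Optional warm-start parameters (default: fresh
#'   initialization).
#' @param seed Optional seed (initialization, batch shuffling).
#' @param verbose Print the per-epoch mean loss.
#' @return List with `params`, per-epoch mean-loss `trace`, and the
#'   neighbor sets `nbrs` used.
#' @export
train_context_encoder <- function(graphs, pairs, labels, config,
                                  params = NULL, seed = NULL,
                                  verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  nbrs <- list(che = build_neighbor_sets(graphs$che, config$nt, config$nk),
               dis = build_neighbor_sets(graphs$dis, config$nt, config$nk))
  if (is.null(params))
    params <- init_context_encoder(graphs$che$n_total, config)
  state <- adam_init(params)
  npair <- nrow(pairs)
  bsz <- min(config$encoder_batch_size, npair)
  trace <- numeric(config$encoder_epochs)
  for (ep in seq_len(config$encoder_epochs)) {
    ord <- sample.int(npair)
    batches <- split(ord, ceiling(seq_along(ord) / bsz))
    eploss <- 0
    for (b in batches) {
      lg <- encoder_loss_grads(params, graphs, nbrs, config,
                               pairs[b, , drop = FALSE], labels[b])
      if (!is.finite(lg$loss))
        stopf("encoder training diverged (non-finite loss) at epoch %d", ep)
      upd <- adam_step(params, lg$grads, state, config$encoder_lr)
      params <- upd$params
      state <- upd$state
      eploss <- eploss + lg$loss
    }
    trace[ep] <- eploss / npair
    if (verbose) message(sprintf("encoder epoch %3d  mean loss %.6f",
                                 ep, trace[ep]))
  }
  list(params = params, trace = trace, nbrs = nbrs)
}
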