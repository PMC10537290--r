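## Analytic backpropagation for the capsule scorer. The routing loop is
## unrolled: every iteration's coupling coefficients, pre-squash sums, and
## digit capsules are retained, and gradients flow through the softmax, the
## squash, and the agreement updates of all earlier iterations. Verified by
## finite differences in the test suite.

squash_backward <- function(o, dv) {
  s2 <- sum(o^2)
  if (s2 == 0) return(dv * 0)
  s <- sqrt(s2)
  cs <- s / (1 + s2)
  cp <- (1 - s2) / (1 + s2)^2
  cs * dv + (cp / s) * o * sum(o * dv)
}

routing_backward <- function(uhat, hist, dv_out) {
  nqn <- length(uhat)
  P <- nrow(uhat[[1L]])
  R <- length(hist)
  db <- matrix(0, P, nqn)
  dU <- lapply(uhat, function(m) m * 0)
  for (r in rev(seq_len(R))) {
    h <- hist[[r]]
    dv <- if (r == R) dv_out else dv_out * 0
    if (r < R) {
      ## the agreement update at round r fed the logits of round r+1
      for (q in seq_len(nqn)) {
        dv[q, ] <- dv[q, ] + as.vector(crossprod(uhat[[q]], db[, q]))
        dU[[q]] <- dU[[q]] + outer(db[, q], h$v[q, ])
      }
    }
    dc <- matrix(0, P, nqn)
    for (q in seq_len(nqn)) {
      do_q <- squash_backward(h$o[q, ], dv[q, ])
      dc[, q] <- uhat[[q]] %*% do_q
      dU[[q]] <- dU[[q]] + outer(h$c[, q], do_q)
    }
    sb <- h$c * (dc - rowSums(h$c * dc))
    db <- sb + db
  }
  dU
}

## Gradients for one sample; label in {0,1}. Returns loss and a parameter
## gradient structure mirroring init_capsule_net().
capsule_sample_grads <- function(params, Z, label, config) {
  fw <- capsule_forward_internal(params, Z, config, keep = TRUE)
  ca <- fw$cache
  nf <- config$nf; w <- config$w; fpg <- config$filters_per_group
  nqd <- config$capsule_dim
  N <- ca$N
  eps <- 1e-12
  loss <- -log(max(fw$prob[label + 1L], eps))
  dnorm <- fw$prob - c(1 - label, label)
  dv <- fw$v * 0
  for (q in 1:2)
    if (ca$norms[q] > 0) dv[q, ] <- dnorm[q] * fw$v[q, ] / ca$norms[q]
  dU <- routing_backward(ca$uhat, ca$hist, dv)
  ## dWcap[p, (d-1)w+k] = dU[p, d] u[p, k]; du[p, k] = sum_{q,d} dU W
  drep <- rep(seq_len(nqd), each = w)
  ksum <- kronecker(rep(1, nqd), diag(w))
  gWcap <- lapply(dU, function(dUq) dUq[, drep, drop = FALSE] * ca$urep)
  du <- (dU[[1L]][, drep, drop = FALSE] * params$Wcap[[1L]] +
         dU[[2L]][, drep, drop = FALSE] * params$Wcap[[2L]]) %*% ksum
  dviews <- matrix(0, w, 2L * N)
  dviews[, ca$pos] <- t(du)
  dH2 <- if (fpg > 1L) dviews[rep(seq_len(w), each = fpg), , drop = FALSE] / fpg
         else dviews
  dH2raw <- dH2 * (ca$raw2 > 0)
  gW2 <- tcrossprod(dH2raw, ca$X)
  gb2 <- rowSums(dH2raw)
  dX <- crossprod(params$W2, dH2raw)
  dH1 <- matrix(0, nf, 3L * (N + 1L))
  o <- 0L
  for (b in 1:2) for (a in 1:2) {
    o <- o + 1L
    base <- (b + seq_len(N) - 2L) * 3L + (a - 1L)
    colsel <- as.vector(rbind(base + 1L, base + 2L))
    rows <- (seq_len(nf) - 1L) * 4L + o
    dH1[, colsel] <- dH1[, colsel] + dX[rows, , drop = FALSE]
  }
  dH1raw <- dH1 * (ca$raw1 > 0)
  list(loss = loss,
       grads = list(W1 = tcrossprod(dH1raw, ca$S1), b1 = rowSums(dH1raw),
                    W2 = gW2, b2 = gb2, Wcap = gWcap))
}

capsule_batch_grads <- function(params, Zs, labels, config) {
  total <- NULL
  loss <- 0
  for (s in seq_along(Zs)) {
    sg <- capsule_sample_grads(params, Zs[[s]], labels[s], config)
    loss <- loss + sg$loss
    total <- if (is.null(total)) sg$grads else grads_add(total, sg$grads)
  }
  list(loss = loss, grads = total)
}

#' Train the capsule scorer
#'
#' Mini-batch Adam on the summed cross-entropy of the capsule association
#' probabilities over labeled pairs. Deterministic given `seed`.
#'
#' @param graphs List with the `che` and `dis` graphs (training association
#'   matrix).
#' @param pairs Two-column (drug, side-effect) index matrix.
#' @param labels 0/1 vector.
#' @param config An [adverank_config()].
#' @param params Optional warm start (default fresh [init_capsule_net()]).
#' @param seed Optional seed.
#' @param verbose Print per-epoch mean loss.
#' @return List with `params` and per-epoch mean-loss `trace`.
#' @export
train_capsule_net <- function(graphs, pairs, labels, config,
                              params = NULL, seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params))
    params <- init_capsule_net(graphs$che$n_total, config)
  Zs <- lapply(seq_len(nrow(pairs)), function(s)
    stacked_pair_embedding(graphs$che, graphs$dis,
                           pairs[s, 1L], pairs[s, 2L]))
  state <- adam_init(params)
  npair <- length(Zs)
  bsz <- min(config$capsule_batch_size, npair)
  trace <- numeric(config$capsule_epochs)
  for (ep in seq_len(config$capsule_epochs)) {
    ord <- sample.int(npair)
    batches <- split(ord, ceiling(seq_along(ord) / bsz))
    eploss <- 0
    for (b in batches) {
      bg <- capsule_batch_grads(params, Zs[b], labels[b], config)
      if (!is.finite(bg$loss))
        stopf("capsule training diverged (non-finite loss) at epoch %d", ep)
      upd <- adam_step(params, bg$grads, state, config$capsule_lr)
      params <- upd$params
      state <- upd$state
      eploss <- eploss + bg$loss
    }
    trace[ep] <- eploss / npair
    if (verbose) message(sprintf("capsule epoch %3d  mean loss %.6f",
                                 ep, trace[ep]))
  }
  list(params = params, trace = trace)
}

#' Capsule association probabilities for a set of pairs
#'
#' @param params Capsule parameters.
#' @param graphs List with the `che` and `dis` graphs.
#' @param pairs Two-column (drug, side-effect) index matrix.
#' @param config An [adverank_config()].
#' @return Numeric vector of association probabilities (component 2 of the
#'   capsule softmax), one per pair.
#' @export
capsule_pair_scores <- function(params, graphs, pairs, config) {
  vapply(seq_len(nrow(pairs)), function(s) {
    Z <- stacked_pair_embedding(graphs$che, graphs$dis,
                                pairs[s, 1L], pairs[s, 2L])
    capsule_forward_internal(params, Z, config)$prob[2L]
  }, numeric(1))
}
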