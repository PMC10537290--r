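# Independent straight-line re-implementations of the model equations,
# written with explicit element loops and no shared code with the package
# internals. They take the same parameter structures so that both routes
# can be run with identical weights and compared to high precision.

oracle_matvec <- function(W, x) {
  out <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) {
    s <- 0
    for (j in seq_len(ncol(W))) s <- s + W[i, j] * x[j]
    out[i] <- s
  }
  out
}

oracle_softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

## neighbor lists recomputed from scratch: self first, then the most
## similar others (descending similarity, ties by ascending index)
oracle_same_neighbors <- function(simrow, i, nt) {
  others <- setdiff(seq_along(simrow), i)
  ord <- others[order(-simrow[others], others)]
  c(i, ord[seq_len(min(nt - 1L, length(ord)))])
}

oracle_forward_graph <- function(gp, X, nr, cfg) {
  N <- nrow(X)
  ns <- N - nr
  Tt <- cfg$heads
  state <- X
  for (l in seq_len(cfg$layers)) {
    lp <- gp$layers[[l]]
    Tn <- cfg$dims[l]
    n <- Tn %/% Tt
    new_state <- matrix(0, N, Tn)
    for (v in seq_len(N)) {
      ## neighbor sets of node v
      if (v <= nr) {
        same <- oracle_same_neighbors(X[v, seq_len(nr)], v, cfg$nt)
        cross <- nr + which(X[v, nr + seq_len(ns)] == 1)
        e_same <- "rr"
      } else {
        same <- nr + oracle_same_neighbors(X[v, nr + seq_len(ns)], v - nr,
                                           cfg$nt)
        cross <- which(X[seq_len(nr), v] == 1)
        e_same <- "ss"
      }
      cross <- cross[seq_len(min(cfg$nk, length(cross)))]
      cats <- list(same = list(members = same, e = e_same))
      if (length(cross) > 0)
        cats$cross <- list(members = c(v, cross), e = "ra")
      y_list <- list()
      for (u in names(cats)) {
        members <- cats[[u]]$members
        y_u <- numeric(0)
        for (t in seq_len(Tt)) {
          rows <- ((t - 1L) * n + 1L):(t * n)
          Wq_t <- lp$Wq[rows, , drop = FALSE]
          Wk_t <- lp$Wk[rows, , drop = FALSE]
          Wv_t <- lp$Wv[rows, , drop = FALSE]
          Wd_t <- lp$Wd[[cats[[u]]$e]][, , t]
          q <- oracle_matvec(Wq_t, state[v, ])
          M <- length(members)
          K <- matrix(0, M, n)
          V <- matrix(0, M, n)
          for (m in seq_len(M)) {
            K[m, ] <- oracle_matvec(Wk_t, state[members[m], ])
            V[m, ] <- oracle_matvec(Wv_t, state[members[m], ])
          }
          alpha <- numeric(M)
          for (m in seq_len(M)) {
            s <- 0
            for (d1 in seq_len(n)) for (d2 in seq_len(n))
              s <- s + K[m, d1] * Wd_t[d1, d2] * q[d2]
            alpha[m] <- if (cfg$scaled_attention) s / sqrt(n) else s
          }
          gam <- oracle_softmax(alpha)
          y_t <- numeric(n)
          for (m in seq_len(M)) y_t <- y_t + gam[m] * V[m, ]
          y_u <- c(y_u, y_t)
        }
        y_list[[u]] <- y_u
      }
      s_cat <- numeric(length(y_list))
      for (ui in seq_along(y_list)) {
        a <- tanh(oracle_matvec(lp$att$W, y_list[[ui]]) + lp$att$b)
        s_cat[ui] <- sum(lp$att$h * a)
      }
      beta <- oracle_softmax(s_cat)
      z <- numeric(Tn)
      for (ui in seq_along(y_list)) z <- z + beta[ui] * y_list[[ui]]
      new_state[v, ] <- z
    }
    state <- new_state
  }
  z_add <- matrix(0, N, ncol(state))
  for (v in seq_len(N))
    z_add[v, ] <- oracle_matvec(gp$res, pmax(X[v, ], 0)) + state[v, ]
  z_add
}

oracle_encoder_pair_prob <- function(params, graphs, nr, cfg, i, j) {
  za_che <- oracle_forward_graph(params$graphs$che, graphs$che$adjacency,
                                 nr, cfg)
  za_dis <- oracle_forward_graph(params$graphs$dis, graphs$dis$adjacency,
                                 nr, cfg)
  w <- params$fusion$w
  zf <- w[1] * za_che + w[2] * za_dis + params$fusion$b
  z_ij <- c(zf[i, ], zf[nr + j, ])
  oracle_softmax(oracle_matvec(params$classifier$W, z_ij) +
                 params$classifier$b)
}

## ---- capsule scorer, element by element ------------------------------------

oracle_squash <- function(o) {
  s <- sqrt(sum(o^2))
  if (s == 0) return(o)
  (s^2 / (1 + s^2)) * o / s
}

oracle_routing <- function(uhat_list, iters) {
  P <- nrow(uhat_list[[1]])
  nqn <- length(uhat_list)
  nqd <- ncol(uhat_list[[1]])
  b <- matrix(0, P, nqn)
  cpq <- NULL; v <- NULL
  for (r in seq_len(iters)) {
    cpq <- matrix(0, P, nqn)
    for (p in seq_len(P)) cpq[p, ] <- oracle_softmax(b[p, ])
    v <- matrix(0, nqn, nqd)
    for (q in seq_len(nqn)) {
      o <- numeric(nqd)
      for (p in seq_len(P)) o <- o + cpq[p, q] * uhat_list[[q]][p, ]
      v[q, ] <- oracle_squash(o)
    }
    for (p in seq_len(P)) for (q in seq_len(nqn))
      b[p, q] <- b[p, q] + sum(uhat_list[[q]][p, ] * v[q, ])
  }
  list(v = v, coupling = cpq)
}

oracle_capsule_prob <- function(params, Z, cfg) {
  N <- ncol(Z)
  nf <- cfg$nf; w <- cfg$w; nqd <- cfg$capsule_dim
  Zhat <- cbind(0, Z, 0)
  ## stage 1: nf filters of 2x2, kernel columns ordered (a fastest, then b)
  H1 <- array(0, c(nf, 3L, N + 1L))
  for (k in seq_len(nf)) for (i in 1:3) for (j in seq_len(N + 1L)) {
    s <- params$b1[k]
    for (b in 1:2) for (a in 1:2)
      s <- s + params$W1[k, (b - 1L) * 2L + a] * Zhat[i + a - 1L, j + b - 1L]
    H1[k, i, j] <- max(s, 0)
  }
  ## stage 2: w groups, each one 2x2 filter over all nf channels
  H2 <- array(0, c(w, 2L, N))
  for (g in seq_len(w)) for (i in 1:2) for (j in seq_len(N)) {
    s <- params$b2[g]
    for (k in seq_len(nf)) for (b in 1:2) for (a in 1:2)
      s <- s + params$W2[g, (k - 1L) * 4L + (b - 1L) * 2L + a] *
        H1[k, i + a - 1L, j + b - 1L]
    H2[g, i, j] <- max(s, 0)
  }
  ## primary capsules, row-major positions
  P <- 2L * N
  u <- matrix(0, P, w)
  for (i in 1:2) for (j in seq_len(N))
    u[(i - 1L) * N + j, ] <- H2[, i, j]
  uhat <- lapply(1:2, function(q) {
    uh <- matrix(0, P, nqd)
    for (p in seq_len(P)) for (d in seq_len(nqd)) {
      s <- 0
      for (k in seq_len(w))
        s <- s + params$Wcap[[q]][p, (d - 1L) * w + k] * u[p, k]
      uh[p, d] <- s
    }
    uh
  })
  rt <- oracle_routing(uhat, cfg$routing_iters)
  norms <- c(sqrt(sum(rt$v[1, ]^2)), sqrt(sum(rt$v[2, ]^2)))
  oracle_softmax(norms)
}

## ---- exhaustive ranking metrics --------------------------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracle_aupr <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  tp <- 0; s <- 0
  for (r in seq_along(lab)) {
    if (lab[r] == 1) {
      tp <- tp + 1
      s <- s + tp / r
    }
  }
  s / sum(labels)
}

max_rel_diff <- function(a, b) {
  d <- abs(a - b)
  sc <- pmax(abs(a), abs(b))
  max(ifelse(sc > 0, d / sc, d))
}
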