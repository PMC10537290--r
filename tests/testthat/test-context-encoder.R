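test_that("same-type neighbor extraction keeps self first and is deterministic", {
  sim <- similarity_matrix(matrix(c(1, .9, .2, .7,
                                    .9, 1, .3, .3,
                                    .2, .3, 1, .6,
                                    .7, .3, .6, 1), 4, byrow = TRUE))
  expect_equal(same_type_neighbors(sim, 1, 3), c(1L, 2L, 4L))
  expect_equal(same_type_neighbors(sim, 1, 1), 1L)
  expect_equal(length(same_type_neighbors(sim, 2, 10)), 4L)
  ## ties broken by ascending index
  tie <- similarity_matrix(matrix(c(1, .5, .5, .5,
                                    .5, 1, .5, .5,
                                    .5, .5, 1, .5,
                                    .5, .5, .5, 1), 4))
  expect_equal(same_type_neighbors(tie, 3, 3), c(3L, 1L, 2L))
  expect_error(same_type_neighbors(sim, 1, 0), "positive")
})

test_that("cross-type neighbor extraction lists associated nodes ascending", {
  A <- association_matrix(matrix(c(1, 0, 1, 1,
                                   0, 0, 0, 0), 2, byrow = TRUE))
  expect_equal(cross_type_neighbors(A, 1, 3, "drug"), c(1L, 3L, 4L))
  expect_equal(cross_type_neighbors(A, 1, 2, "drug"), c(1L, 3L))
  expect_equal(cross_type_neighbors(A, 2, 3, "drug"), integer(0))
  expect_equal(cross_type_neighbors(A, 4, 5, "side_effect"), 1L)
  expect_error(cross_type_neighbors(A, 1, -1), "non-negative")
})

test_that("query/key/value maps are plain linear maps in member order", {
  set.seed(5)
  W <- matrix(rnorm(8), 2, 4)
  x <- rnorm(4)
  manual <- c(sum(W[1, ] * x), sum(W[2, ] * x))
  expect_equal(head_query(W, x), manual)
  expect_equal(head_query(W, numeric(4)), c(0, 0))
  expect_error(head_query(W, numeric(3)), "state has length")

  states <- matrix(rnorm(12), 3, 4)
  kv <- head_keys_values(W, W * 2, states)
  expect_equal(dim(kv$K), c(3L, 2L))
  for (m in 1:3) expect_equal(kv$K[m, ], head_query(W, states[m, ]))
  expect_equal(kv$V, 2 * kv$K)
  perm <- c(3, 1, 2)
  expect_equal(head_keys_values(W, W, states[perm, ])$K, kv$K[perm, ])
  expect_error(head_keys_values(W, W, states[0, , drop = FALSE]), "non-empty")
})

test_that("semantic attention scores are the bilinear form K W_d q", {
  set.seed(6)
  K <- matrix(rnorm(12), 4, 3)
  q <- rnorm(3)
  Wd <- matrix(rnorm(9), 3, 3)
  brute <- numeric(4)
  for (m in 1:4)
    for (d1 in 1:3) for (d2 in 1:3)
      brute[m] <- brute[m] + K[m, d1] * Wd[d1, d2] * q[d2]
  expect_equal(semantic_attention_scores(K, q, Wd), brute)
  expect_equal(semantic_attention_scores(K, 2 * q, Wd), 2 * brute)
  expect_equal(semantic_attention_scores(K, q, Wd, scaled = TRUE),
               brute / sqrt(3))
  ## orthogonal keys with identity semantics give zero scores
  Ko <- rbind(c(0, 1, 0), c(0, 0, 1))
  expect_equal(semantic_attention_scores(Ko, c(1, 0, 0), diag(3)), c(0, 0))
  expect_error(semantic_attention_scores(K, q, diag(2)), "shape")
})

test_that("softmax aggregation normalizes and is permutation-equivariant", {
  V <- matrix(c(1, 0, 0, 1, 2, 2), 3, 2, byrow = TRUE)
  eq <- normalize_and_aggregate(c(3, 3, 3), V)
  expect_equal(eq$weights, rep(1 / 3, 3))
  expect_equal(eq$context, colMeans(V))

  two <- normalize_and_aggregate(c(1, 2), V[1:2, ])
  expect_equal(round(two$weights, 4), c(0.2689, 0.7311))
  expect_equal(sum(two$weights), 1)

  one <- normalize_and_aggregate(5, V[3, , drop = FALSE])
  expect_equal(one$weights, 1)
  expect_equal(one$context, V[3, ])

  ## permuting members leaves the aggregate unchanged
  set.seed(8)
  sc <- rnorm(5); Vm <- matrix(rnorm(10), 5, 2)
  perm <- sample(5)
  expect_equal(normalize_and_aggregate(sc, Vm)$context,
               normalize_and_aggregate(sc[perm], Vm[perm, ])$context)
  ## large scores do not overflow
  expect_equal(sum(normalize_and_aggregate(c(1000, 999), Vm[1:2, ])$weights), 1)
})

test_that("head concatenation preserves order and dimension", {
  expect_equal(concat_heads(list(c(1, 2))), c(1, 2))
  expect_equal(concat_heads(list(c(1, 2, 3), c(4, 5, 6))), 1:6)
  expect_error(concat_heads(list(c(1, 2), NULL)), "present")
  expect_error(concat_heads(list(c(1, 2), c(1, 2, 3))), "differ")
})

test_that("category attention follows the tanh bottleneck closed form", {
  att <- list(W = diag(2), b = c(0, 0), h = c(1, 0))
  y1 <- c(0.3, -1); y2 <- c(-0.2, 5)
  ca <- category_attention(list(same = y1, cross = y2), att)
  s_manual <- c(tanh(0.3), tanh(-0.2))
  beta_manual <- exp(s_manual) / sum(exp(s_manual))
  expect_equal(unname(ca$s), s_manual)
  expect_equal(unname(ca$beta), beta_manual)
  expect_equal(ca$output, beta_manual[1] * y1 + beta_manual[2] * y2)
  expect_equal(sum(ca$beta), 1)

  same <- category_attention(list(a = y1, b = y1), att)
  expect_equal(unname(same$beta), c(0.5, 0.5))
  expect_equal(same$output, y1)

  single <- category_attention(list(same = y2), att)
  expect_equal(unname(single$beta), 1)
  expect_equal(single$output, y2)
})

test_that("residual projection and graph fusion are the documented affine maps", {
  W <- matrix(c(1, 0, 2,
                0, 1, -1), 2, byrow = TRUE)
  x <- c(1, 0, .5)
  z <- c(10, 20)
  expect_equal(residual_projection(W, x, z), c(sum(W[1, ] * x), sum(W[2, ] * x)) + z)
  expect_equal(residual_projection(W * 0, x, z), z)
  ## relu only matters for (malformed) negative attributes
  expect_equal(residual_projection(W, c(-1, 0, .5), z),
               residual_projection(W, c(0, 0, .5), z))

  expect_equal(graph_fusion(c(1, 1), c(3, 4), c(1, 0)), c(1, 1))
  expect_equal(graph_fusion(c(2, 2), c(2, 2), c(.5, .5)), c(2, 2))
  expect_equal(graph_fusion(c(1, 2), c(3, 4), c(.3, .7)), c(2.4, 3.4))
  expect_error(graph_fusion(1, 2, c(1, 2, 3)), "length 2")
})

test_that("encoder pair probabilities come from a softmax over two logits", {
  cls <- list(W = matrix(0, 2, 4), b = c(0, 0))
  expect_equal(encoder_score(cls, c(1, 2), c(3, 4)), c(0.5, 0.5))
  cls$b <- c(0, log(3))
  expect_equal(encoder_score(cls, c(1, 2), c(3, 4)), c(0.25, 0.75))
  set.seed(9)
  cls2 <- list(W = matrix(rnorm(8), 2, 4), b = rnorm(2))
  p <- encoder_score(cls2, rnorm(2), rnorm(2))
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
})

test_that("attention and category weights normalize throughout a full forward", {
  gs <- fixture_graphs()
  cfg <- tiny_config()
  params <- init_context_encoder(gs$che$n_total, cfg, seed = 21)
  nbrs <- list(che = build_neighbor_sets(gs$che, cfg$nt, cfg$nk),
               dis = build_neighbor_sets(gs$dis, cfg$nt, cfg$nk))
  fwd <- context_encoder_forward(params, gs, nbrs, cfg, keep_cache = TRUE)
  for (side in c("che", "dis")) {
    expect_equal(fwd[[side]]$states[[1]], gs[[side]]$adjacency,
                 ignore_attr = TRUE)
    for (l in seq_len(cfg$layers)) for (v in seq_len(gs$che$n_total)) {
      ch <- fwd[[side]]$caches[[l]][[v]]
      expect_equal(sum(ch$beta), 1)
      for (u in names(ch$cats))
        expect_equal(unname(colSums(ch$cats[[u]]$gamma)),
                     rep(1, cfg$heads), tolerance = 1e-12)
    }
  }
})

test_that("layer-2 parameters do not affect layer-1 states", {
  gs <- fixture_graphs()
  cfg <- tiny_config()
  params <- init_context_encoder(gs$che$n_total, cfg, seed = 3)
  nbrs <- list(che = build_neighbor_sets(gs$che, cfg$nt, cfg$nk),
               dis = build_neighbor_sets(gs$dis, cfg$nt, cfg$nk))
  f1 <- context_encoder_forward(params, gs, nbrs, cfg)
  params2 <- params
  params2$graphs$che$layers[[2]]$Wq <- params2$graphs$che$layers[[2]]$Wq * 2
  f2 <- context_encoder_forward(params2, gs, nbrs, cfg)
  expect_equal(f1$che$states[[2]], f2$che$states[[2]])
  expect_false(isTRUE(all.equal(f1$che$states[[3]], f2$che$states[[3]])))
})

test_that("isolated nodes with no associations still get an encoding", {
  A <- association_matrix(rbind(c(1, 1, 0), c(0, 0, 0)))  # drug 2 isolated
  D <- similarity_matrix(matrix(c(1, .2, .2, 1), 2))
  S <- similarity_matrix(diag(3))
  gs <- list(che = build_adjacency(D, A, S, "che"),
             dis = build_adjacency(D, A, S, "dis"))
  cfg <- adverank_config(nt = 2, nk = 3, layers = 1, heads = 1, dims = 4,
                         att_dim = 3)
  params <- init_context_encoder(5, cfg, seed = 2)
  nbrs <- list(che = build_neighbor_sets(gs$che, 2, 3),
               dis = build_neighbor_sets(gs$dis, 2, 3))
  fwd <- context_encoder_forward(params, gs, nbrs, cfg, keep_cache = TRUE)
  expect_true(all(is.finite(fwd$z_fin)))
  ## isolated drug has one category with weight 1
  ch <- fwd$che$caches[[1]][[2]]
  expect_equal(names(ch$cats), "same")
  expect_equal(unname(ch$beta), 1)
})

test_that("analytic encoder gradients match finite differences", {
  gs <- fixture_graphs()
  cfg <- tiny_config()
  nbrs <- list(che = build_neighbor_sets(gs$che, cfg$nt, cfg$nk),
               dis = build_neighbor_sets(gs$dis, cfg$nt, cfg$nk))
  params <- init_context_encoder(gs$che$n_total, cfg, seed = 11)
  pairs <- cbind(c(1, 2, 5), c(1, 4, 7))
  labels <- c(1, 1, 0)
  lg <- adverank:::encoder_loss_grads(params, gs, nbrs, cfg, pairs, labels)
  loss_of <- function(p)
    adverank:::encoder_loss_grads(p, gs, nbrs, cfg, pairs, labels)$loss
  path_get <- function(x, path) {
    for (p in path) x <- x[[p]]
    x
  }
  path_mod <- function(x, path, idx, delta) {
    if (length(path) == 1L) {
      x[[path[[1]]]][idx] <- x[[path[[1]]]][idx] + delta
    } else {
      x[[path[[1]]]] <- path_mod(x[[path[[1]]]], path[-1L], idx, delta)
    }
    x
  }
  paths <- list(
    list("graphs", "che", "layers", 1L, "Wq"),
    list("graphs", "dis", "layers", 2L, "Wk"),
    list("graphs", "che", "layers", 1L, "Wd", "rr"),
    list("graphs", "dis", "layers", 2L, "Wd", "ra"),
    list("graphs", "che", "layers", 2L, "att", "W"),
    list("graphs", "che", "res"),
    list("fusion", "w"),
    list("classifier", "W"))
  set.seed(31)
  for (path in paths) {
    val <- path_get(params, path)
    for (idx in sample(length(val), min(3, length(val)))) {
      eps <- 1e-6
      num <- (loss_of(path_mod(params, path, idx, eps)) -
              loss_of(path_mod(params, path, idx, -eps))) / (2 * eps)
      ana <- path_get(lg$grads, path)[idx]
      expect_equal(ana, num, tolerance = 1e-4,
                   label = paste("grad", paste(unlist(path), collapse = "/"),
                                 idx))
    }
  }
})

test_that("encoder training reduces the loss deterministically", {
  gs <- fixture_graphs()
  cfg <- tiny_config(encoder_epochs = 15, encoder_lr = 5e-3, seed = 2)
  A <- gs$che$adjacency[1:6, 6 + 1:8]
  pos <- which(A == 1)
  set.seed(1)
  neg <- sample(which(A == 0), length(pos))
  idx <- c(pos, neg)
  pairs <- cbind((idx - 1) %% 6 + 1, (idx - 1) %/% 6 + 1)
  labels <- rep(c(1, 0), c(length(pos), length(neg)))
  tr1 <- train_context_encoder(gs, pairs, labels, cfg, seed = 42)
  tr2 <- train_context_encoder(gs, pairs, labels, cfg, seed = 42)
  expect_identical(tail(tr1$trace, 1), tail(tr2$trace, 1))
  expect_lt(tail(tr1$trace, 1), tr1$trace[1])
  ## zero epochs returns the initial parameters unchanged
  cfg0 <- tiny_config(encoder_epochs = 0)
  set.seed(42)
  tr0 <- train_context_encoder(gs, pairs, labels, cfg0)
  set.seed(42)
  nb <- list(che = build_neighbor_sets(gs$che, cfg0$nt, cfg0$nk),
             dis = build_neighbor_sets(gs$dis, cfg0$nt, cfg0$nk))
  ref <- init_context_encoder(gs$che$n_total, cfg0)
  expect_identical(tr0$params, ref)
})
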