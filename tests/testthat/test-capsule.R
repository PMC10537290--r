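test_that("stage-1 convolution enumerates filter placements correctly", {
  N <- 5L
  filt <- array(1, c(2, 2, 1))
  zero <- conv_stage1(matrix(0, 4, N), filt)
  expect_equal(dim(zero), c(1L, 3L, N + 1L))
  expect_true(all(zero == 0))

  ## single 1 at padded position (1, 2): covered by windows whose 2x2
  ## patch contains it
  Z <- matrix(0, 4, N); Z[1, 1] <- 1
  out <- conv_stage1(Z, filt)
  hit <- matrix(0, 3, N + 1)
  for (i in 1:3) for (j in seq_len(N + 1))
    if (i <= 1 && j %in% c(1, 2) && i + 1 >= 1 && j + 1 >= 2)
      hit[i, j] <- 1
  expect_equal(out[1, , ], hit)

  ## shape law: nf x (4 - wf + 1) x (2 + N - lf + 1)
  set.seed(2)
  f2 <- array(rnorm(2 * 2 * 6), c(2, 2, 6))
  expect_equal(dim(conv_stage1(matrix(rnorm(4 * N), 4), f2, rnorm(6))),
               c(6L, 3L, N + 1L))
  expect_error(conv_stage1(matrix(0, 4, 2), array(1, c(5, 2, 1))), "larger")
})

test_that("stage-2 convolution reduces channels into one view per group", {
  maps0 <- array(0, c(3, 3, 4))
  f <- array(1, c(2, 2, 3, 1))
  expect_true(all(conv_stage2(maps0, f) == 0))

  ## hand toy: one input channel, N_total = 2, explicit window sums
  set.seed(3)
  m <- array(rnorm(1 * 3 * 3), c(1, 3, 3))
  fk <- array(rnorm(4), c(2, 2, 1, 1))
  out <- conv_stage2(m, fk)
  expect_equal(dim(out), c(1L, 2L, 2L))
  for (i in 1:2) for (j in 1:2) {
    s <- 0
    for (a in 1:2) for (b in 1:2)
      s <- s + fk[a, b, 1, 1] * m[1, i + a - 1, j + b - 1]
    expect_equal(out[1, i, j], max(s, 0))
  }

  ## default geometry: w = 8 groups over nf = 64 channels
  maps <- array(rnorm(64 * 3 * 6), c(64, 3, 6))
  f8 <- array(rnorm(2 * 2 * 64 * 8), c(2, 2, 64, 8))
  expect_equal(dim(conv_stage2(maps, f8, rnorm(8))), c(8L, 2L, 5L))
  expect_error(conv_stage2(maps, array(0, c(2, 2, 32, 8))), "nf")
})

test_that("primary capsules collect per-position values across views", {
  views <- array(0, c(2, 2, 3))      # w = 2 views, grid 2 x 3
  views[1, , ] <- matrix(1:6, 2, byrow = TRUE)
  views[2, , ] <- matrix(7:12, 2, byrow = TRUE)
  u <- form_primary_capsules(views)
  expect_equal(dim(u), c(6L, 2L))    # P = 2 * N_total
  for (i in 1:2) for (j in 1:3)
    expect_equal(u[(i - 1) * 3 + j, ], c(views[1, i, j], views[2, i, j]))
  ## permuting views permutes capsule coordinates identically
  expect_equal(form_primary_capsules(views[2:1, , ]), u[, 2:1])
})

test_that("squash has the closed-form norm and is monotone", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  o1 <- c(1, 0) / sqrt(1)           # unit norm
  expect_equal(sqrt(sum(squash(o1)^2)), 0.5)
  set.seed(4)
  for (rep in 1:20) {
    o <- rnorm(5) * 10^runif(1, -2, 2)
    v <- squash(o)
    n_o <- sqrt(sum(o^2))
    expect_equal(sqrt(sum(v^2)), n_o^2 / (1 + n_o^2))
    expect_equal(v * n_o, o * sqrt(sum(v^2)))  # parallel
    expect_lt(sqrt(sum(v^2)), 1)
  }
  ## norm strictly increasing in the input norm
  grid <- seq(0.01, 50, length.out = 1000)
  norms <- vapply(grid, function(s) sqrt(sum(squash(c(s, 0))^2)), numeric(1))
  expect_true(all(diff(norms) > 0))
})

test_that("dynamic routing matches the loop oracle and degenerates correctly", {
  ## uniform first-round coupling from zero logits
  set.seed(5)
  uh <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  r1 <- dynamic_routing(uh, 1)
  expect_equal(r1$coupling, matrix(0.5, 4, 2))

  ## single digit capsule: coupling 1, v = squash of the plain sum
  uh1 <- list(matrix(rnorm(8), 4, 2))
  rs <- dynamic_routing(array(uh1[[1]], c(4, 1, 2)), 3)
  expect_equal(unname(rs$coupling), matrix(1, 4, 1))
  expect_equal(rs$v[1, ], squash(colSums(uh1[[1]])))

  ## hand-set P=2, n_qn=2, n_qd=2, three iterations vs the oracle
  uh2 <- list(matrix(c(1, -2, 0.5, 3), 2), matrix(c(0.3, 1, -1, 0.2), 2))
  uh2_arr <- array(0, c(2, 2, 2))       # [p, q, d]
  uh2_arr[, 1, ] <- uh2[[1]]
  uh2_arr[, 2, ] <- uh2[[2]]
  pk <- dynamic_routing(uh2_arr, 3)
  or <- oracle_routing(uh2, 3)
  expect_equal(pk$v, or$v, tolerance = 1e-12)
  expect_equal(pk$coupling, or$coupling, tolerance = 1e-12)
  expect_equal(rowSums(pk$coupling), rep(1, 2))
})

test_that("capsule probabilities are the norm softmax", {
  v_eq <- rbind(c(0.3, 0.4), c(0.5, 0))     # both norms 0.5
  expect_equal(capsule_score(v_eq), c(0.5, 0.5))
  v2 <- rbind(c(0, 0), c(log(2), 0))
  expect_equal(capsule_score(v2), c(1 / 3, 2 / 3))
  set.seed(6)
  p <- capsule_score(matrix(rnorm(8), 2))
  expect_equal(sum(p), 1)
})

test_that("the conv/capsule shape chain holds for several graph sizes", {
  cfg <- adverank_config(nf = 5, w = 3, capsule_dim = 4)
  for (N in c(5L, 10L, 50L)) {
    params <- init_capsule_net(N, cfg, seed = 7)
    Z <- matrix(runif(4 * N), 4, N)
    fw <- adverank:::capsule_forward_internal(params, Z, cfg, keep = TRUE)
    expect_equal(dim(fw$cache$H1), c(5L, 3L * (N + 1L)))
    expect_equal(dim(fw$cache$views), c(3L, 2L * N))
    expect_equal(dim(fw$cache$u), c(2L * N, 3L))       # P = 2 N_total
    expect_equal(dim(fw$v), c(2L, 4L))
    expect_equal(sum(fw$prob), 1)
    expect_equal(rowSums(fw$coupling), rep(1, 2L * N))
  }
})

test_that("full capsule forward matches the straight-line oracle", {
  cfg <- adverank_config(nf = 4, w = 3, capsule_dim = 5, routing_iters = 3)
  N <- 10L
  params <- init_capsule_net(N, cfg, seed = 8)
  set.seed(9)
  Z <- matrix(runif(4 * N), 4, N)
  fw <- capsule_forward(params, Z, cfg)
  expect_lt(max_rel_diff(fw$prob, oracle_capsule_prob(params, Z, cfg)), 1e-10)
})

test_that("analytic capsule gradients match finite differences", {
  gs <- fixture_graphs()
  cfg <- tiny_config()
  params <- init_capsule_net(gs$che$n_total, cfg, seed = 5)
  ## move biases off zero so no relu argument sits exactly on the kink
  set.seed(10)
  params$b1 <- rnorm(cfg$nf, 0, 0.1)
  params$b2 <- rnorm(cfg$w, 0, 0.1)
  Z <- stacked_pair_embedding(gs$che, gs$dis, 2, 3)
  sg <- adverank:::capsule_sample_grads(params, Z, 1L, cfg)
  loss_of <- function(p) -log(max(capsule_forward(p, Z, cfg)$prob[2], 1e-12))
  for (nm in c("W1", "b1", "W2", "b2")) {
    val <- params[[nm]]
    for (idx in sample(length(val), min(4, length(val)))) {
      eps <- 1e-6
      p1 <- params; p1[[nm]][idx] <- p1[[nm]][idx] + eps
      p2 <- params; p2[[nm]][idx] <- p2[[nm]][idx] - eps
      num <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
      expect_equal(sg$grads[[nm]][idx], num, tolerance = 1e-4,
                   label = paste("grad", nm, idx))
    }
  }
  for (q in 1:2) {
    ## check coordinates with non-zero gradient (zero primary capsules
    ## legitimately produce zero columns)
    live <- which(sg$grads$Wcap[[q]] != 0)
    for (idx in live[sample.int(length(live), min(4, length(live)))]) {
      eps <- 1e-6
      p1 <- params; p1$Wcap[[q]][idx] <- p1$Wcap[[q]][idx] + eps
      p2 <- params; p2$Wcap[[q]][idx] <- p2$Wcap[[q]][idx] - eps
      num <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
      expect_equal(sg$grads$Wcap[[q]][idx], num, tolerance = 1e-4)
    }
  }
})

test_that("the filters-per-group expansion keeps shapes and exact gradients", {
  cfg <- tiny_config(filters_per_group = 2)
  N <- 7L
  params <- init_capsule_net(N, cfg, seed = 14)
  expect_equal(dim(params$W2), c(cfg$w * 2L, 4L * cfg$nf))
  set.seed(15)
  params$b1 <- rnorm(cfg$nf, 0, 0.1)
  params$b2 <- rnorm(cfg$w * 2L, 0, 0.1)
  Z <- matrix(runif(4 * N), 4, N)
  fw <- adverank:::capsule_forward_internal(params, Z, cfg, keep = TRUE)
  expect_equal(dim(fw$cache$views), c(cfg$w, 2L * N))
  expect_equal(sum(fw$prob), 1)
  sg <- adverank:::capsule_sample_grads(params, Z, 0L, cfg)
  loss_of <- function(p) -log(max(capsule_forward(p, Z, cfg)$prob[1], 1e-12))
  for (idx in sample(length(params$W2), 4)) {
    eps <- 1e-6
    p1 <- params; p1$W2[idx] <- p1$W2[idx] + eps
    p2 <- params; p2$W2[idx] <- p2$W2[idx] - eps
    num <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
    expect_equal(sg$grads$W2[idx], num, tolerance = 1e-4)
  }
})

test_that("capsule training reduces the loss deterministically", {
  gs <- fixture_graphs()
  cfg <- tiny_config(capsule_epochs = 10, capsule_lr = 1e-2,
                     capsule_batch_size = 16)
  A <- gs$che$adjacency[1:6, 6 + 1:8]
  pos <- which(A == 1)
  set.seed(2)
  neg <- sample(which(A == 0), length(pos))
  idx <- c(pos, neg)
  pairs <- cbind((idx - 1) %% 6 + 1, (idx - 1) %/% 6 + 1)
  labels <- rep(c(1, 0), c(length(pos), length(neg)))
  tr1 <- train_capsule_net(gs, pairs, labels, cfg, seed = 12)
  tr2 <- train_capsule_net(gs, pairs, labels, cfg, seed = 12)
  expect_identical(tr1$trace, tr2$trace)
  expect_lt(tail(tr1$trace, 1), tr1$trace[1])
})
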