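## Capsule scorer: scores one drug--side-effect pair from its stacked raw
## pair embeddings (4 x N_total: drug/che, side-effect, drug/dis,
## side-effect). Two convolution stages extract local cross-row features,
## the w view maps are folded position-wise into 2*N_total primary capsules
## of dimension w, and routing-by-agreement distributes them onto two digit
## capsules whose norms (after softmax) give the association probability.

## One zero column on each side of the length axis only; this is the
## padding consistent with the stage-1 output shape (4-wf+1 rows, no row
## padding; 2+N-lf+1 columns).
pad_pair_embedding <- function(Z) {
  cbind(numeric(nrow(Z)), Z, numeric(nrow(Z)))
}

## Gather matrix for a valid 2-D cross-correlation: rows are kernel offsets
## (a fastest, then b), columns are output positions (i fastest, then j).
conv_gather <- function(M, wf, lf, out_r, out_c) {
  S <- matrix(0, wf * lf, out_r * out_c)
  r <- 0L
  for (b in seq_len(lf)) for (a in seq_len(wf)) {
    r <- r + 1L
    S[r, ] <- as.vector(M[a:(a + out_r - 1L), b:(b + out_c - 1L)])
  }
  S
}

#' First convolution stage over a stacked pair embedding
#'
#' Pads the `4 x N_total` map with one zero column on each side of the
#' length axis, then applies `nf` valid cross-correlations with relu
#' activation. Output shape is `nf x (4 - wf + 1) x (2 + N_total - lf + 1)`.
#'
#' @param Z Stacked pair embedding (`4 x N_total`), see
#'   [stacked_pair_embedding()].
#' @param filters Kernel array of dimension `(wf, lf, nf)` (rows x columns
#'   x filters).
#' @param bias Numeric vector of length `nf`.
#' @return 3-D array `nf x (4-wf+1) x (2+N_total-lf+1)`.
#' @export
conv_stage1 <- function(Z, filters, bias = NULL) {
  if (nrow(Z) != 4L) stopf("stacked pair embedding must have 4 rows")
  d <- dim(filters)
  if (length(d) != 3L) stopf("filters must be a (wf, lf, nf) array")
  wf <- d[1L]; lf <- d[2L]; nf <- d[3L]
  Zhat <- pad_pair_embedding(Z)
  if (wf > nrow(Zhat) || lf > ncol(Zhat))
    stopf("filter (%dx%d) larger than the padded input (%dx%d)",
          wf, lf, nrow(Zhat), ncol(Zhat))
  bias <- bias %||% numeric(nf)
  out_r <- 4L - wf + 1L
  out_c <- ncol(Zhat) - lf + 1L
  S <- conv_gather(Zhat, wf, lf, out_r, out_c)
  Wmat <- t(matrix(filters, wf * lf, nf))
  raw <- Wmat %*% S + bias
  array(relu(raw), dim = c(nf, out_r, out_c))
}

#' Second convolution stage: w view maps
#'
#' Each of the `w` groups applies one 2x2 valid convolution summing over the
#' `nf` input channels, with relu, yielding one `2 x N_total` view map.
#'
#' @param maps Stage-1 output (`nf x 3 x (N_total + 1)` array).
#' @param filters Kernel array of dimension `(2, 2, nf, w)`.
#' @param bias Numeric vector of length `w`.
#' @return 3-D array `w x 2 x N_total`.
#' @export
conv_stage2 <- function(maps, filters, bias = NULL) {
  d <- dim(maps)
  fd <- dim(filters)
  if (length(fd) != 4L || fd[1L] != 2L || fd[2L] != 2L)
    stopf("filters must be a (2, 2, nf, w) array")
  if (length(d) != 3L || d[2L] != 3L || fd[3L] != d[1L])
    stopf("stage-1 maps must be nf x 3 x (N_total + 1) with nf = %d", fd[3L])
  nf <- d[1L]; w <- fd[4L]
  N <- d[3L] - 1L
  bias <- bias %||% numeric(w)
  X <- conv2_gather(maps, N)
  Wmat <- t(matrix(filters, 4L * nf, w))
  raw <- Wmat %*% X + bias
  array(relu(raw), dim = c(w, 2L, N))
}

## Gather the stage-1 maps into a (4*nf) x (2*N_total) matrix whose row
## order matches the column-major flattening of a (2, 2, nf) kernel
## (offset a fastest, then b, then channel k).
conv2_gather <- function(maps, N) {
  nf <- dim(maps)[1L]
  X <- matrix(0, 4L * nf, 2L * N)
  o <- 0L
  for (b in 1:2) for (a in 1:2) {
    o <- o + 1L
    sub <- maps[, a:(a + 1L), b:(b + N - 1L), drop = FALSE]
    X[(seq_len(nf) - 1L) * 4L + o, ] <- matrix(sub, nf, 2L * N)
  }
  X
}

#' Fold view maps into primary capsules
#'
#' The p-th primary capsule collects the value at grid position p (row-major
#' over the `2 x N_total` grid) across all `w` view maps, giving
#' `P = 2 * N_total` capsules of dimension `w`.
#'
#' @param views View array (`w x 2 x N_total`) from [conv_stage2()].
#' @return Matrix `P x w`, one capsule per row.
#' @export
form_primary_capsules <- function(views) {
  d <- dim(views)
  if (length(d) != 3L || d[2L] != 2L)
    stopf("views must form a w x 2 x N_total array")
  w <- d[1L]; N <- d[3L]
  u <- matrix(0, 2L * N, w)
  for (i in 1:2) for (j in seq_len(N))
    u[(i - 1L) * N + j, ] <- views[, i, j]
  u
}

#' Squash non-linearity
#'
#' Rescales a vector to norm `||o||^2 / (1 + ||o||^2)` (always in `[0,1)`),
#' preserving direction; the zero vector maps to itself (guarded division).
#'
#' @param o Numeric vector.
#' @return Vector parallel to `o` with squashed norm.
#' @export
squash <- function(o) {
  s2 <- sum(o^2)
  if (s2 == 0) return(o)
  (s2 / (1 + s2)) * o / sqrt(s2)
}

## Routing-by-agreement with full iteration history (needed for the
## unrolled backward pass). uhat: list over digit capsules q of P x n_qd
## prediction matrices.
routing_forward <- function(uhat, iters) {
  P <- nrow(uhat[[1L]])
  nqn <- length(uhat)
  nqd <- ncol(uhat[[1L]])
  b <- matrix(0, P, nqn)
  hist <- vector("list", iters)
  cpq <- NULL; v <- NULL
  for (r in seq_len(iters)) {
    cpq <- softmax_rows(b)
    o <- matrix(0, nqn, nqd)
    v <- matrix(0, nqn, nqd)
    for (q in seq_len(nqn)) {
      o[q, ] <- .colSums(cpq[, q] * uhat[[q]], P, nqd)
      v[q, ] <- squash(o[q, ])
    }
    hist[[r]] <- list(c = cpq, o = o, v = v)
    for (q in seq_len(nqn)) b[, q] <- b[, q] + uhat[[q]] %*% v[q, ]
  }
  list(v = v, coupling = cpq, hist = hist)
}

#' Dynamic routing between capsule layers
#'
#' Routing-by-agreement: routing logits start at zero; each of the `iters`
#' rounds softmax-normalizes them over the digit capsules into coupling
#' coefficients (summing to 1 for every primary capsule), forms each digit
#' capsule as the squashed coupling-weighted sum of predictions, and
#' reinforces the logits by the prediction--output agreement.
#'
#' @param uhat Prediction vectors, either a 3-D array
#'   (`P x n_qn x n_qd`) or a list over digit capsules of `P x n_qd`
#'   matrices.
#' @param iters Number of routing iterations (>= 1).
#' @return List with `v` (`n_qn x n_qd` digit capsules) and `coupling`
#'   (`P x n_qn`, rows sum to 1).
#' @export
dynamic_routing <- function(uhat, iters) {
  if (!is_count(iters)) stopf("iters must be a positive integer")
  if (is.array(uhat) && length(dim(uhat)) == 3L) {
    uhat <- lapply(seq_len(dim(uhat)[2L]), function(q) uhat[, q, ])
    uhat <- lapply(uhat, function(m) if (is.matrix(m)) m else matrix(m, ncol = 1L))
  }
  rf <- routing_forward(uhat, iters)
  rf[c("v", "coupling")]
}

#' Association probability from digit capsules
#'
#' Softmax over the digit-capsule norms; capsule 1 encodes "not associated",
#' the last capsule "associated".
#'
#' @param v Digit capsule matrix (`n_qn x n_qd`).
#' @return Probability vector summing to 1.
#' @export
capsule_score <- function(v) {
  softmax(sqrt(rowSums(v^2)))
}

#' Initialize capsule-scorer parameters
#'
#' @param n_total Number of graph nodes (pair-embedding length; the primary
#'   capsule count is `2 * n_total`).
#' @param config An [adverank_config()].
#' @param seed Optional seed.
#' @return Parameter list (`W1`, `b1`, `W2`, `b2`, `Wcap`).
#' @export
init_capsule_net <- function(n_total, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- config$nf; w <- config$w
  fpg <- config$filters_per_group
  nqd <- config$capsule_dim
  P <- 2L * n_total
  acap <- sqrt(6 / (w + nqd))
  list(W1 = glorot(nf, 4L),
       b1 = numeric(nf),
       W2 = glorot(w * fpg, 4L * nf),
       b2 = numeric(w * fpg),
       Wcap = lapply(1:2, function(q)
         matrix(stats::runif(P * nqd * w, -acap, acap), P, nqd * w)))
}

## Fast internal forward on matrix layouts; keep = TRUE retains every
## intermediate needed by the backward pass.
capsule_forward_internal <- function(params, Z, config, keep = FALSE) {
  N <- ncol(Z)
  nf <- config$nf; w <- config$w; fpg <- config$filters_per_group
  nqd <- config$capsule_dim
  Zhat <- pad_pair_embedding(Z)
  S1 <- conv_gather(Zhat, 2L, 2L, 3L, N + 1L)
  raw1 <- params$W1 %*% S1 + params$b1
  H1 <- relu(raw1)                              # nf x 3(N+1)
  maps <- array(H1, dim = c(nf, 3L, N + 1L))
  X <- conv2_gather(maps, N)                    # 4nf x 2N
  raw2 <- params$W2 %*% X + params$b2           # (w*fpg) x 2N
  H2 <- relu(raw2)
  views <- if (fpg > 1L) {
    grp <- rep(seq_len(w), each = fpg)
    rowsum(H2, grp) / fpg
  } else H2                                     # w x 2N
  ## primary capsules: row-major grid position p -> flat column (j-1)*2+i
  pos <- as.vector(t(matrix(seq_len(2L * N), 2L, N)))
  u <- t(views[, pos, drop = FALSE])            # P x w
  ## uhat[p, d] = sum_k Wcap[p, (d-1)w+k] u[p, k], all d at once: expand u
  ## across the d blocks and fold with a block-sum matrix
  urep <- u[, rep(seq_len(w), nqd), drop = FALSE]
  bsum <- kronecker(diag(nqd), rep(1, w))
  uhat <- lapply(params$Wcap, function(W) (W * urep) %*% bsum)
  rf <- routing_forward(uhat, config$routing_iters)
  norms <- sqrt(rowSums(rf$v^2))
  prob <- softmax(norms)
  out <- list(prob = prob, v = rf$v, coupling = rf$coupling)
  if (keep)
    out$cache <- list(S1 = S1, raw1 = raw1, H1 = H1, X = X, raw2 = raw2,
                      H2 = H2, views = views, pos = pos, u = u, urep = urep,
                      uhat = uhat, hist = rf$hist, norms = norms, N = N)
  out
}

#' Capsule-scorer forward pass for one pair
#'
#' Runs the full convolution / primary-capsule / routing chain on a stacked
#' pair embedding and returns the association probability pair.
#'
#' @param params Parameters from [init_capsule_net()].
#' @param Z Stacked pair embedding (`4 x N_total`).
#' @param config An [adverank_config()].
#' @return List with `prob` (length 2, sums to 1; component 2 is the
#'   association probability), digit capsules `v`, and `coupling`.
#' @export
capsule_forward <- function(params, Z, config) {
  capsule_forward_internal(params, Z, config, keep = FALSE)
}
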