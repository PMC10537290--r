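## Adam optimizer over arbitrarily nested parameter lists. Parameters and
## gradients are parallel nested lists of numeric arrays; moment estimates
## mirror the same structure.

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  p * 0
}

## Element-wise walk over two parallel nested lists.
walk2 <- function(a, b, f) {
  if (is.list(a)) return(Map(function(x, y) walk2(x, y, f), a, b))
  f(a, b)
}

walk3 <- function(a, b, c, f) {
  if (is.list(a)) return(Map(function(x, y, z) walk3(x, y, z, f), a, b, c))
  f(a, b, c)
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

## One Adam update; returns list(params, state).
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- walk2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- walk2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  params <- walk3(params, state$m, state$v, function(p, m, v)
    p - lr * (m * c1) / (sqrt(v * c2) + eps))
  list(params = params, state = state)
}

## Sum two parallel gradient structures.
grads_add <- function(a, b) walk2(a, b, `+`)
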