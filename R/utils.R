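#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Numerically stable softmax
#'
#' Softmax with max-subtraction so that large scores do not overflow
#' `exp()`. Operates on a plain numeric vector.
#'
#' @param x Numeric vector of scores.
#' @return Numeric vector of the same length, non-negative, summing to 1.
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

## Row-wise stable softmax for a matrix of logits. max.col() gives the
## row maxima in C speed (apply() dominates profiles here otherwise).
softmax_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

## Column-wise stable softmax (each column normalized over rows).
softmax_cols <- function(m) {
  tm <- t(m)
  mx <- tm[cbind(seq_len(nrow(tm)), max.col(tm, ties.method = "first"))]
  e <- exp(m - rep(mx, each = nrow(m)))
  e / rep(colSums(e), each = nrow(m))
}

relu <- function(x) pmax(x, 0)

## Glorot-style uniform init for a weight matrix of shape nrow x ncol
## (fan_out x fan_in); fan-based uniform is the standard transformer and
## capsule-network default.
glorot <- function(nrow, ncol) {
  a <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -a, a), nrow, ncol)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

`%||%` <- function(a, b) if (is.null(a)) b else a
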