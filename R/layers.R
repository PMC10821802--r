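# Dense-layer primitives used by both transformer channels. Every forward
# returns list(out, cache); the matching backward takes (d_out, cache) and
# returns list(d_in, grads) where grads is a named list keyed like the
# parameter names it was given.

linear_forward <- function(x, W, b = NULL) {
  out <- x %*% W
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  list(out = out, cache = list(x = x, W = W, has_b = !is.null(b)))
}

linear_backward <- function(d_out, cache) {
  d_in <- d_out %*% t(cache$W)
  dW <- crossprod(cache$x, d_out)
  grads <- list(W = dW)
  if (cache$has_b) grads$b <- colSums(d_out)
  list(d_in = d_in, grads = grads)
}

LN_EPS <- 1e-5

layernorm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  out <- sweep(xhat, 2L, g, "*")
  out <- sweep(out, 2L, b, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_backward <- function(d_out, cache) {
  g <- cache$g; xhat <- cache$xhat; inv <- cache$inv
  D <- ncol(xhat)
  d_xhat <- sweep(d_out, 2L, g, "*")
  # standard layer-norm backward: project out the mean and the xhat component
  t1 <- rowSums(d_xhat) / D
  t2 <- rowSums(d_xhat * xhat) / D
  d_in <- (d_xhat - t1 - xhat * t2) * inv
  list(d_in = d_in,
       grads = list(g = colSums(d_out * xhat), b = colSums(d_out)))
}

gelu_forward <- function(x) {
  out <- x * stats::pnorm(x)
  list(out = out, cache = x)
}

gelu_backward <- function(d_out, cache) {
  x <- cache
  d_out * (stats::pnorm(x) + x * stats::dnorm(x))
}

# Row-wise softmax tolerating -Inf logits (blocked attention pairs get
# exactly zero mass).
softmax_rows <- function(a) {
  m <- apply(a, 1L, max)
  e <- exp(a - m)
  e / rowSums(e)
}

# d_a given d_p for row-wise softmax p = softmax(a).
softmax_rows_backward <- function(d_p, p) {
  p * (d_p - rowSums(d_p * p))
}

log_softmax_vec <- function(z) {
  m <- max(z)
  z - m - log(sum(exp(z - m)))
}
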