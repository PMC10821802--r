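# Windowed multi-head self-attention with relative position bias.
#
# Attention parameters are a nested list:
#   list(qkv = list(W, b), proj = list(W, b), rpb = matrix)
# where W_qkv is D x 3D (queries, keys, values side by side), W_proj is
# D x D, and rpb is the (2M-1)^2 x heads relative position bias table.

#' Initialize attention parameters for one block
#'
#' @param D token dimension; `heads` number of attention heads; `M` window
#'   size; `rpb` whether to allocate a relative position bias table.
#' @return nested parameter list.
#' @export
init_attention_params <- function(D, heads, M, rpb = TRUE) {
  if (D %% heads != 0L)
    stop("token dim ", D, " not divisible by head count ", heads)
  p <- list(
    qkv = list(W = trunc_normal(D, 3L * D), b = numeric(3L * D)),
    proj = list(W = trunc_normal(D, D), b = numeric(D))
  )
  p$rpb <- if (rpb) matrix(trunc_normal_vec((2L * M - 1L)^2 * heads),
                           (2L * M - 1L)^2, heads)
           else matrix(0, (2L * M - 1L)^2, heads)
  p
}

trunc_normal_vec <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

trunc_normal <- function(nr, nc, sd = 0.02) {
  matrix(trunc_normal_vec(nr * nc, sd), nr, nc)
}

# Core forward. grid: N x D token matrix with grid attributes. Returns
# list(out, cache); cache = NULL when want_cache = FALSE.
msa_forward <- function(grid, p, heads, M, shift = 0L, want_cache = TRUE) {
  gh <- attr(grid, "grid_h"); gw <- attr(grid, "grid_w")
  D <- ncol(grid)
  if (D %% heads != 0L) stop("token dim not divisible by head count")
  d <- D %/% heads
  scale <- 1 / sqrt(d)
  idx <- partition_index(gh, gw, M, shift)
  xw <- grid[idx, , drop = FALSE]
  qkv <- linear_forward(xw, p$qkv$W, p$qkv$b)
  Q <- qkv$out[, 1:D, drop = FALSE]
  K <- qkv$out[, D + (1:D), drop = FALSE]
  V <- qkv$out[, 2L * D + (1:D), drop = FALSE]
  rpi <- relative_position_index(M)
  masks <- shift_attention_mask(gh, gw, M, shift)
  nw <- (gh %/% M) * (gw %/% M)
  m2 <- M * M
  O <- matrix(0, nrow(xw), D)
  Ps <- if (want_cache) vector("list", nw * heads)
  for (w in seq_len(nw)) {
    rows <- (w - 1L) * m2 + seq_len(m2)
    blocked <- !masks[[w]]
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * d + seq_len(d)
      A <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) * scale
      A <- A + matrix(p$rpb[rpi, h], m2, m2)
      if (any(blocked)) A[blocked] <- -Inf
      P <- softmax_rows(A)
      O[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
      if (want_cache) Ps[[(w - 1L) * heads + h]] <- P
    }
  }
  proj <- linear_forward(O, p$proj$W, p$proj$b)
  out <- matrix(0, nrow(grid), D)
  out[idx, ] <- proj$out
  out <- token_grid(out, gh, gw)
  cache <- if (want_cache)
    list(idx = idx, qkv_cache = qkv$cache, proj_cache = proj$cache,
         Q = Q, K = K, V = V, Ps = Ps, rpi = rpi, heads = heads, M = M,
         d = d, scale = scale, nw = nw, D = D, gh = gh, gw = gw)
  list(out = out, cache = cache)
}

msa_backward <- function(d_out, cache) {
  ch <- cache
  d_proj_in <- d_out[ch$idx, , drop = FALSE]
  pb <- linear_backward(d_proj_in, ch$proj_cache)
  dO <- pb$d_in
  m2 <- ch$M * ch$M
  dQ <- matrix(0, nrow(dO), ch$D)
  dK <- dQ; dV <- dQ
  d_rpb <- matrix(0, (2L * ch$M - 1L)^2, ch$heads)
  rpi_v <- as.vector(ch$rpi)
  for (w in seq_len(ch$nw)) {
    rows <- (w - 1L) * m2 + seq_len(m2)
    for (h in seq_len(ch$heads)) {
      cols <- (h - 1L) * ch$d + seq_len(ch$d)
      P <- ch$Ps[[(w - 1L) * ch$heads + h]]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- ch$V[rows, cols, drop = FALSE]
      dV[rows, cols] <- crossprod(P, dOh)
      dP <- tcrossprod(dOh, Vh)
      dA <- softmax_rows_backward(dP, P)
      acc <- rowsum(as.vector(dA), rpi_v)
      ii <- as.integer(rownames(acc))
      d_rpb[ii, h] <- d_rpb[ii, h] + acc[, 1]
      dQ[rows, cols] <- dA %*% ch$K[rows, cols, drop = FALSE] * ch$scale
      dK[rows, cols] <- crossprod(dA, ch$Q[rows, cols, drop = FALSE]) *
        ch$scale
    }
  }
  qb <- linear_backward(cbind(dQ, dK, dV), ch$qkv_cache)
  d_grid <- matrix(0, nrow(qb$d_in), ch$D)
  d_grid[ch$idx, ] <- qb$d_in
  list(d_in = token_grid(d_grid, ch$gh, ch$gw),
       grads = list(qkv = qb$grads, proj = pb$grads, rpb = d_rpb))
}

#' Window-based multi-head self-attention (W-MSA)
#'
#' Scaled-dot-product attention restricted to non-overlapping `M x M`
#' windows, with a learned relative position bias per head. Output
#' geometry equals input geometry.
#'
#' @param grid N x D token grid (see [token_grid()]).
#' @param weights attention parameters from [init_attention_params()].
#' @param heads number of heads (must divide D).
#' @param M window size in tokens.
#' @return N x D token grid.
#' @export
w_msa <- function(grid, weights, heads, M) {
  msa_forward(grid, weights, heads, M, shift = 0L, want_cache = FALSE)$out
}

#' Shifted-window multi-head self-attention (SW-MSA)
#'
#' Rolls the grid cyclically by `floor(M/2)` in both directions, applies
#' windowed attention with a mask that blocks pairs brought together only
#' by the wrap-around, and rolls back. Successive W-MSA/SW-MSA layers let
#' information cross the regular window boundaries. With `shift = 0` this
#' reduces exactly to [w_msa()].
#'
#' @inheritParams w_msa
#' @param shift cyclic displacement in tokens; default `floor(M/2)`.
#' @return N x D token grid.
#' @export
sw_msa <- function(grid, weights, heads, M, shift = floor(M / 2)) {
  msa_forward(grid, weights, heads, M, shift = as.integer(shift),
              want_cache = FALSE)$out
}

#' Normalized attention maps of a shifted-window layer
#'
#' Returns the per-window, per-head post-softmax attention matrices
#' together with the pre-shift window provenance of each token, for
#' auditing the masking scheme.
#'
#' @inheritParams sw_msa
#' @return list with `P` (list over windows x heads), `provenance`
#'   (pre-shift window id per window-ordered token) and `masks`.
#' @export
attention_audit <- function(grid, weights, heads, M, shift = floor(M / 2)) {
  res <- msa_forward(grid, weights, heads, M, shift = as.integer(shift),
                     want_cache = TRUE)
  gh <- attr(grid, "grid_h"); gw <- attr(grid, "grid_w")
  list(P = res$cache$Ps, heads = heads, M = M,
       provenance = provenance_ids(gh, gw, M, as.integer(shift)),
       masks = shift_attention_mask(gh, gw, M, as.integer(shift)))
}
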