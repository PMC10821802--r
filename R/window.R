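# Window geometry for shifted-window attention.
#
# A token grid is stored as an N x D matrix, N = grid_h * grid_w, tokens in
# row-major order (token (r, c) -> row (r-1)*grid_w + c, 1-based, origin
# top-left). Window partitioning is expressed as an index permutation so the
# backward pass is the inverse permutation.

# Index vector mapping window-ordered positions to original token rows.
# Position p enumerates windows row-major, then tokens row-major within each
# M x M window, after a cyclic roll of the grid by (-shift, -shift).
partition_index <- function(grid_h, grid_w, M, shift = 0L) {
  if (grid_h %% M != 0L || grid_w %% M != 0L)
    stop("grid ", grid_h, "x", grid_w, " is not divisible by window size ", M)
  rr <- (rep(seq_len(grid_h), each = grid_w) - 1L + shift) %% grid_h  # 0-based
  cc <- (rep(seq_len(grid_w), times = grid_h) - 1L + shift) %% grid_w
  # (rr, cc) is the original 0-based coordinate sitting at rolled position p0
  orig <- rr * grid_w + cc + 1L
  # reorder rolled row-major positions into window-major order
  p0 <- seq_len(grid_h * grid_w) - 1L
  r <- p0 %/% grid_w; c <- p0 %% grid_w
  win <- (r %/% M) * (grid_w %/% M) + (c %/% M)
  within <- (r %% M) * M + (c %% M)
  orig[order(win, within)]
}

#' Partition a token grid into attention windows
#'
#' Tiles the grid into non-overlapping `M x M` windows; with a nonzero
#' `shift` the grid is first rolled cyclically by `(-shift, -shift)`, which
#' is how shifted-window attention reuses the regular tiling.
#'
#' @param grid N x D token matrix with attributes `grid_h`, `grid_w`
#'   (see [token_grid()]).
#' @param M window side length in tokens.
#' @param shift cyclic shift in tokens (0 for regular windows).
#' @return A `window_set`: list with `windows` (an `M^2 x D x n_windows`
#'   array), the permutation `index`, and the originating geometry.
#' @export
window_partition <- function(grid, M, shift = 0L) {
  gh <- attr(grid, "grid_h"); gw <- attr(grid, "grid_w")
  idx <- partition_index(gh, gw, M, shift)
  xw <- grid[idx, , drop = FALSE]
  nw <- (gh %/% M) * (gw %/% M)
  structure(list(
    windows = array(t(xw), dim = c(ncol(grid), M * M, nw)),
    index = idx, grid_h = gh, grid_w = gw, M = M, shift = shift
  ), class = "window_set")
}

#' Reassemble a token grid from a window set
#'
#' Inverse of [window_partition()] (including the cyclic roll):
#' `window_reverse(window_partition(g, M, s))` is `g` for every shift.
#'
#' @param ws a `window_set`.
#' @return N x D token matrix with grid attributes restored.
#' @export
window_reverse <- function(ws) {
  D <- dim(ws$windows)[1]
  xw <- t(matrix(ws$windows, nrow = D))
  out <- matrix(0, ws$grid_h * ws$grid_w, D)
  out[ws$index, ] <- xw
  token_grid(out, ws$grid_h, ws$grid_w)
}

#' Construct a token grid
#'
#' @param x N x D numeric matrix (N = grid_h * grid_w, row-major tokens).
#' @param grid_h,grid_w grid dimensions in tokens.
#' @return the matrix with `grid_h`/`grid_w` attributes set.
#' @export
token_grid <- function(x, grid_h, grid_w) {
  stopifnot(nrow(x) == grid_h * grid_w)
  attr(x, "grid_h") <- grid_h
  attr(x, "grid_w") <- grid_w
  x
}

# Region labels distinguishing wrapped from unwrapped content in the rolled
# frame. Rolled rows/cols fall in [0, g-M), [g-M, g-shift) or [g-shift, g);
# tokens of different labels were not spatially adjacent in the original
# image (they meet only through the cyclic wrap) and must not attend to
# each other.
shift_region_ids <- function(grid_h, grid_w, M, shift) {
  band <- function(n) {
    p <- seq_len(n) - 1L
    ifelse(p < n - M, 0L, ifelse(p < n - shift, 1L, 2L))
  }
  rb <- band(grid_h); cb <- band(grid_w)
  outer(rb, cb, function(r, c) 3L * r + c)
}

#' Attention admissibility mask for shifted windows
#'
#' For each window of the rolled grid, an `M^2 x M^2` logical matrix:
#' `TRUE` where the token pair may attend. With `shift = 0` all pairs are
#' admissible. With a nonzero shift, pairs whose members were brought
#' together by the cyclic wrap (they originate from opposite edges of the
#' image, hence from disjoint pre-shift windows) are blocked; their
#' post-softmax attention weight is exactly zero.
#'
#' @param grid_h,grid_w grid size in tokens.
#' @param M window size; `shift` cyclic shift.
#' @return list of logical matrices, one per window (row-major window order).
#' @export
shift_attention_mask <- function(grid_h, grid_w, M, shift) {
  nw <- (grid_h %/% M) * (grid_w %/% M)
  if (shift == 0L)
    return(rep(list(matrix(TRUE, M * M, M * M)), nw))
  ids <- shift_region_ids(grid_h, grid_w, M, shift)
  masks <- vector("list", nw)
  k <- 1L
  for (wr in seq_len(grid_h %/% M)) {
    for (wc in seq_len(grid_w %/% M)) {
      sub <- ids[(wr - 1L) * M + seq_len(M), (wc - 1L) * M + seq_len(M)]
      v <- as.vector(t(sub))  # row-major within-window order
      masks[[k]] <- outer(v, v, "==")
      k <- k + 1L
    }
  }
  masks
}

# Pre-shift (regular-tiling) window id of each token in window-major order,
# used by tests to audit provenance of masked pairs.
provenance_ids <- function(grid_h, grid_w, M, shift) {
  idx <- partition_index(grid_h, grid_w, M, shift)
  p0 <- idx - 1L
  r <- p0 %/% grid_w; c <- p0 %% grid_w
  (r %/% M) * (grid_w %/% M) + (c %/% M)
}

# M^2 x M^2 matrix of 1-based indices into the (2M-1)^2-row relative
# position bias table, from within-window row-major coordinates.
relative_position_index <- function(M) {
  r <- rep(seq_len(M) - 1L, each = M)
  c <- rep(seq_len(M) - 1L, times = M)
  dr <- outer(r, r, "-") + M - 1L
  dc <- outer(c, c, "-") + M - 1L
  dr * (2L * M - 1L) + dc + 1L
}
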