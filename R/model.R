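#' Architecture configuration for one transformer channel
#'
#' Defaults are the Swin-T-style geometry used throughout: 224x224 input,
#' 4x4 patches (48-dim raw tokens), embedding width `C = 96`, window size
#' `M = 7`, four stages of depths 2/2/6/2 with heads 3/6/12/24, and channel
#' width doubling at each patch merge (96/192/384/768), giving stage grids
#' 56/28/14/7 and a pooled feature of length `8C = 768`.
#'
#' Window size is clamped per stage to the stage grid (a 7x7 final grid
#' with `M = 7` is a single window, where no shift is applied).
#'
#' @param image_size input side length in pixels (square input).
#' @param patch_size patch side length in pixels.
#' @param embed_dim embedding width C of stage 1.
#' @param window_size window side length M in tokens.
#' @param depths integer vector, number of blocks per stage (each even so
#'   regular/shifted blocks pair up).
#' @param heads integer vector, attention heads per stage.
#' @param num_classes number of target classes.
#' @param mlp_ratio hidden-width multiplier of the block MLP.
#' @param drop_path_rate maximal stochastic-depth rate (0 = deterministic).
#' @param use_rpb include a learned relative position bias.
#' @return object of class `swin_config`.
#' @export
swin_config <- function(image_size = 224L, patch_size = 4L, embed_dim = 96L,
                        window_size = 7L, depths = c(2L, 2L, 6L, 2L),
                        heads = c(3L, 6L, 12L, 24L), num_classes = 22L,
                        mlp_ratio = 4, drop_path_rate = 0,
                        use_rpb = TRUE) {
  stopifnot(length(depths) == length(heads), all(depths >= 1),
            num_classes >= 2, image_size >= patch_size)
  ns <- length(depths)
  if (image_size %% (patch_size * 2^(ns - 1L)) != 0L)
    stop("image size ", image_size, " not divisible by patch_size * 2^",
         ns - 1L)
  grids <- image_size %/% patch_size %/% (2^(seq_len(ns) - 1L))
  M_eff <- pmin(window_size, grids)
  if (any(grids %% M_eff != 0L))
    stop("stage grids (", paste(grids, collapse = ", "),
         ") not divisible by window size ", window_size)
  dims <- embed_dim * 2^(seq_len(ns) - 1L)
  if (any(dims %% heads != 0L))
    stop("stage dims not divisible by head counts")
  structure(list(
    image_size = as.integer(image_size), patch_size = as.integer(patch_size),
    embed_dim = as.integer(embed_dim), window_size = as.integer(window_size),
    depths = as.integer(depths), heads = as.integer(heads),
    num_classes = as.integer(num_classes), mlp_ratio = mlp_ratio,
    drop_path_rate = drop_path_rate, use_rpb = isTRUE(use_rpb),
    n_stages = ns, stage_grids = as.integer(grids),
    stage_dims = as.integer(dims), stage_windows = as.integer(M_eff),
    feature_dim = as.integer(dims[ns])
  ), class = "swin_config")
}

#' Partition an image into patch tokens
#'
#' Cuts the image into non-overlapping `patch_size x patch_size` squares
#' and flattens each into one token by concatenating its pixel values
#' (channel-major, then patch row, then patch column), so a 4x4 RGB patch
#' yields a 48-dimensional token.
#'
#' @param image H x W x 3 numeric array.
#' @param patch_size patch side length; must divide both image dimensions.
#' @return token grid of shape (H/patch * W/patch) x (patch^2 * 3).
#' @export
patch_partition <- function(image, patch_size) {
  check_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]; P <- as.integer(patch_size)
  if (H %% P != 0L || W %% P != 0L)
    stop("image ", H, "x", W, " not divisible by patch size ", P)
  gh <- H %/% P; gw <- W %/% P
  tok <- matrix(0, gh * gw, P * P * 3L)
  for (ch in 1:3) for (pr in seq_len(P)) for (pc in seq_len(P)) {
    k <- ((ch - 1L) * P + (pr - 1L)) * P + pc
    sub <- image[seq(pr, H, by = P), seq(pc, W, by = P), ch, drop = TRUE]
    tok[, k] <- as.vector(t(sub))
  }
  token_grid(tok, gh, gw)
}

# Scatter token gradients back to image pixels (exact adjoint of
# patch_partition, which is a permutation of entries).
patch_partition_backward <- function(d_tok, H, W, P) {
  gh <- H %/% P; gw <- W %/% P
  d_img <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) for (pr in seq_len(P)) for (pc in seq_len(P)) {
    k <- ((ch - 1L) * P + (pr - 1L)) * P + pc
    d_img[seq(pr, H, by = P), seq(pc, W, by = P), ch] <-
      matrix(d_tok[, k], gh, gw, byrow = TRUE)
  }
  d_img
}

#' Linear patch embedding
#'
#' Projects raw patch tokens (dim `patch^2 * 3`) to the working width C.
#'
#' @param tokens token grid from [patch_partition()].
#' @param weights list with `W` (in x C) and `b` (length C).
#' @return token grid of the same geometry with dim C.
#' @export
linear_embed <- function(tokens, weights) {
  out <- linear_forward(tokens, weights$W, weights$b)$out
  token_grid(out, attr(tokens, "grid_h"), attr(tokens, "grid_w"))
}

merge_gather_index <- function(gh, gw) {
  nh <- gh %/% 2L; nw <- gw %/% 2L
  r <- rep(seq_len(nh), each = nw); c <- rep(seq_len(nw), times = nh)
  at <- function(dr, dc) (2L * (r - 1L) + dr) * gw + 2L * (c - 1L) + dc + 1L
  # official gather order: (0,0), (1,0), (0,1), (1,1)
  list(at(0L, 0L), at(1L, 0L), at(0L, 1L), at(1L, 1L))
}

patch_merge_forward <- function(x, p, want_cache = TRUE) {
  gh <- attr(x, "grid_h"); gw <- attr(x, "grid_w")
  if (gh %% 2L != 0L || gw %% 2L != 0L)
    stop("patch merging requires an even token grid, got ", gh, "x", gw)
  idx <- merge_gather_index(gh, gw)
  x4 <- cbind(x[idx[[1]], , drop = FALSE], x[idx[[2]], , drop = FALSE],
              x[idx[[3]], , drop = FALSE], x[idx[[4]], , drop = FALSE])
  ln <- layernorm_forward(x4, p$norm$g, p$norm$b)
  red <- linear_forward(ln$out, p$reduce$W)
  out <- token_grid(red$out, gh %/% 2L, gw %/% 2L)
  cache <- if (want_cache) list(idx = idx, ln = ln$cache, red = red$cache,
                                gh = gh, gw = gw, D = ncol(x))
  list(out = out, cache = cache)
}

patch_merge_backward <- function(d_out, cache) {
  rb <- linear_backward(d_out, cache$red)
  lb <- layernorm_backward(rb$d_in, cache$ln)
  D <- cache$D
  d_x <- matrix(0, cache$gh * cache$gw, D)
  for (k in 1:4)
    d_x[cache$idx[[k]], ] <- d_x[cache$idx[[k]], ] +
      lb$d_in[, (k - 1L) * D + seq_len(D), drop = FALSE]
  list(d_in = token_grid(d_x, cache$gh, cache$gw),
       grads = list(norm = lb$grads, reduce = list(W = rb$grads$W)))
}

#' Merge 2x2 token neighborhoods
#'
#' Concatenates each 2x2 neighborhood into a 4C-vector, layer-normalizes
#' it and reduces it linearly to 2C, halving the grid in both directions.
#' This is the down-sampling step between stages.
#'
#' @param grid token grid with even dimensions.
#' @param weights list with `norm` (g, b over 4C) and `reduce` (`W`,
#'   4C x 2C, no bias).
#' @return token grid of shape (gh/2 * gw/2) x 2C.
#' @export
patch_merge <- function(grid, weights) {
  patch_merge_forward(grid, weights, want_cache = FALSE)$out
}

init_layernorm_params <- function(D) list(g = rep(1, D), b = numeric(D))

# Output projections of both residual branches start at zero, so every
# block is initially the identity map and the network escapes the
# uniform-logit saddle quickly during CPU-scale training; the projections
# receive nonzero gradients from the first step onward.
init_block_params <- function(D, heads, M, mlp_ratio, use_rpb) {
  hidden <- round(mlp_ratio * D)
  p <- list(
    norm1 = init_layernorm_params(D),
    attn = init_attention_params(D, heads, M, rpb = use_rpb),
    norm2 = init_layernorm_params(D),
    mlp = list(fc1 = list(W = trunc_normal(D, hidden), b = numeric(hidden)),
               fc2 = list(W = matrix(0, hidden, D), b = numeric(D)))
  )
  p$attn$proj$W[] <- 0
  p$attn$proj$b[] <- 0
  p
}

#' Initialize the parameters of one transformer channel
#'
#' Linear weights are truncated-normal (sd 0.02), biases zero, layer-norm
#' gains one. Consumes the R random stream, so seed before calling for
#' reproducible models.
#'
#' @param config a [swin_config()].
#' @return nested parameter list.
#' @export
init_channel_params <- function(config) {
  cf <- config
  in_dim <- cf$patch_size^2 * 3L
  stages <- vector("list", cf$n_stages)
  for (s in seq_len(cf$n_stages)) {
    D <- cf$stage_dims[s]
    blocks <- lapply(seq_len(cf$depths[s]), function(i)
      init_block_params(D, cf$heads[s], cf$stage_windows[s], cf$mlp_ratio,
                        cf$use_rpb))
    names(blocks) <- paste0("block", seq_len(cf$depths[s]))
    st <- list(blocks = blocks)
    if (s < cf$n_stages)
      st$merge <- list(norm = init_layernorm_params(4L * D),
                       reduce = list(W = trunc_normal(4L * D, 2L * D)))
    stages[[s]] <- st
  }
  names(stages) <- paste0("stage", seq_len(cf$n_stages))
  list(
    patch_embed = list(
      proj = list(W = trunc_normal(in_dim, cf$embed_dim),
                  b = numeric(cf$embed_dim)),
      norm = init_layernorm_params(cf$embed_dim)),
    stages = stages,
    norm = init_layernorm_params(cf$feature_dim)
  )
}

block_forward <- function(x, p, heads, M, shift, drop_keep = 1,
                          want_cache = TRUE) {
  gh <- attr(x, "grid_h"); gw <- attr(x, "grid_w")
  ln1 <- layernorm_forward(x, p$norm1$g, p$norm1$b)
  att <- msa_forward(token_grid(ln1$out, gh, gw), p$attn, heads, M, shift,
                     want_cache = want_cache)
  h <- x + drop_keep * att$out
  ln2 <- layernorm_forward(h, p$norm2$g, p$norm2$b)
  f1 <- linear_forward(ln2$out, p$mlp$fc1$W, p$mlp$fc1$b)
  ge <- gelu_forward(f1$out)
  f2 <- linear_forward(ge$out, p$mlp$fc2$W, p$mlp$fc2$b)
  out <- token_grid(h + drop_keep * f2$out, gh, gw)
  cache <- if (want_cache)
    list(ln1 = ln1$cache, att = att$cache, ln2 = ln2$cache, f1 = f1$cache,
         ge = ge$cache, f2 = f2$cache, drop_keep = drop_keep,
         gh = gh, gw = gw)
  list(out = out, cache = cache)
}

block_backward <- function(d_out, cache) {
  dk <- cache$drop_keep
  f2b <- linear_backward(d_out * dk, cache$f2)
  geb <- gelu_backward(f2b$d_in, cache$ge)
  f1b <- linear_backward(geb, cache$f1)
  ln2b <- layernorm_backward(f1b$d_in, cache$ln2)
  d_h <- d_out + ln2b$d_in
  attb <- msa_backward(d_h * dk, cache$att)
  ln1b <- layernorm_backward(attb$d_in, cache$ln1)
  d_x <- token_grid(d_h + ln1b$d_in, cache$gh, cache$gw)
  list(d_in = d_x,
       grads = list(norm1 = ln1b$grads, attn = attb$grads,
                    norm2 = ln2b$grads, mlp = list(fc1 = f1b$grads,
                                                   fc2 = f2b$grads)))
}

#' Apply one transformer block
#'
#' Pre-normalization residual composition: layer norm, then windowed
#' (`kind = "standard"`) or shifted-window (`kind = "shifted"`) attention,
#' residual add; then layer norm, two-layer GELU MLP, residual add. With
#' zero-initialized attention and MLP output projections the block is the
#' identity map.
#'
#' @param grid token grid.
#' @param kind `"standard"` (W-MSA) or `"shifted"` (SW-MSA).
#' @param weights block parameters from `init_block_params` shape.
#' @param heads,M attention geometry.
#' @return token grid of identical shape.
#' @export
swin_block <- function(grid, kind = c("standard", "shifted"), weights,
                       heads, M) {
  kind <- match.arg(kind)
  shift <- if (kind == "shifted") floor(M / 2) else 0L
  gh <- attr(grid, "grid_h"); gw <- attr(grid, "grid_w")
  if (shift > 0L && (gh <= M && gw <= M)) shift <- 0L
  block_forward(grid, weights, heads, M, as.integer(shift),
                want_cache = FALSE)$out
}

# Per-block stochastic-depth keep factors; deterministic 1s unless training
# with a positive rate.
drop_keep_factors <- function(config, training) {
  nb <- sum(config$depths)
  rates <- seq(0, config$drop_path_rate, length.out = nb)
  if (!training || config$drop_path_rate <= 0) return(rep(1, nb))
  keep <- stats::rbinom(nb, 1L, 1 - rates)
  ifelse(keep == 1L, 1 / (1 - rates), 0)
}

#' Forward pass of one channel
#'
#' Patch partition, linear embedding (plus an embedding layer norm), four
#' stages of alternating standard/shifted blocks with patch merging in
#' between, final layer norm, and global average pooling over the token
#' grid into a single feature vector of length `feature_dim` (768 for the
#' default configuration).
#'
#' @param image H x W x 3 numeric array matching `config$image_size`.
#' @param config a [swin_config()].
#' @param params channel parameters from [init_channel_params()].
#' @param want_cache keep intermediate state for back-propagation.
#' @param training enable stochastic depth if configured.
#' @return list with `feature` (numeric vector), `stage_grids` (realized
#'   stage resolutions) and, when requested, `cache`.
#' @export
channel_forward <- function(image, config, params, want_cache = FALSE,
                            training = FALSE) {
  cf <- config
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H != cf$image_size || W != cf$image_size)
    stop("image is ", H, "x", W, " but config expects ", cf$image_size,
         "x", cf$image_size)
  tok <- patch_partition(image, cf$patch_size)
  gh <- attr(tok, "grid_h"); gw <- attr(tok, "grid_w")
  emb <- linear_forward(tok, params$patch_embed$proj$W,
                        params$patch_embed$proj$b)
  en <- layernorm_forward(emb$out, params$patch_embed$norm$g,
                          params$patch_embed$norm$b)
  x <- token_grid(en$out, gh, gw)
  dks <- drop_keep_factors(cf, training)
  bi <- 0L
  stage_caches <- vector("list", cf$n_stages)
  stage_grids <- integer(cf$n_stages)
  for (s in seq_len(cf$n_stages)) {
    M <- cf$stage_windows[s]
    g <- attr(x, "grid_h")
    stage_grids[s] <- g
    block_caches <- vector("list", cf$depths[s])
    for (i in seq_len(cf$depths[s])) {
      bi <- bi + 1L
      shift <- if (i %% 2L == 0L) floor(M / 2) else 0L
      if (g <= M) shift <- 0L  # single window: shifting is a no-op
      bf <- block_forward(x, params$stages[[s]]$blocks[[i]], cf$heads[s],
                          M, as.integer(shift), dks[bi], want_cache)
      x <- bf$out
      block_caches[[i]] <- bf$cache
    }
    merge_cache <- NULL
    if (s < cf$n_stages) {
      mf <- patch_merge_forward(x, params$stages[[s]]$merge, want_cache)
      x <- mf$out
      merge_cache <- mf$cache
    }
    stage_caches[[s]] <- list(blocks = block_caches, merge = merge_cache)
  }
  fn <- layernorm_forward(x, params$norm$g, params$norm$b)
  feature <- colMeans(fn$out)
  cache <- if (want_cache)
    list(stage_caches = stage_caches, final_ln = fn$cache,
         n_tokens = nrow(x), emb = emb$cache, emb_norm = en$cache,
         H = H, W = W, P = cf$patch_size, config = cf)
  list(feature = feature, stage_grids = stage_grids, cache = cache)
}

channel_backward <- function(d_feature, cache) {
  cf <- cache$config
  d_x <- matrix(d_feature / cache$n_tokens, nrow = cache$n_tokens,
                ncol = length(d_feature), byrow = TRUE)
  fnb <- layernorm_backward(d_x, cache$final_ln)
  g <- cf$stage_grids[cf$n_stages]
  d_x <- token_grid(fnb$d_in, g, g)
  grads <- list(norm = fnb$grads, stages = vector("list", cf$n_stages))
  names(grads$stages) <- paste0("stage", seq_len(cf$n_stages))
  for (s in rev(seq_len(cf$n_stages))) {
    sc <- cache$stage_caches[[s]]
    sg <- list()
    if (!is.null(sc$merge)) {
      mb <- patch_merge_backward(d_x, sc$merge)
      d_x <- mb$d_in
      sg$merge <- mb$grads
    }
    bg <- vector("list", length(sc$blocks))
    for (i in rev(seq_along(sc$blocks))) {
      bb <- block_backward(d_x, sc$blocks[[i]])
      d_x <- bb$d_in
      bg[[i]] <- bb$grads
    }
    names(bg) <- paste0("block", seq_along(sc$blocks))
    sg$blocks <- bg
    grads$stages[[s]] <- sg
  }
  enb <- layernorm_backward(d_x, cache$emb_norm)
  emb <- linear_backward(enb$d_in, cache$emb)
  grads$patch_embed <- list(proj = emb$grads, norm = enb$grads)
  d_image <- patch_partition_backward(emb$d_in, cache$H, cache$W, cache$P)
  list(d_image = d_image, grads = grads)
}

#' Self-attention cost of global versus windowed attention
#'
#' Multiply-accumulate counts of one multi-head self-attention layer on an
#' h x w token grid of width C: global attention costs
#' `4 h w C^2 + 2 (h w)^2 C` (quadratic in the token count), windowed
#' attention with M x M windows costs `4 h w C^2 + 2 M^2 h w C` (linear in
#' the token count). In the single-window limit `M^2 = h w` the two
#' coincide.
#'
#' @param h,w token-grid height and width.
#' @param C channel width.
#' @param M window size.
#' @return list with `omega_msa` and `omega_wmsa`.
#' @export
complexity_estimate <- function(h, w, C, M) {
  vals <- c(h, w, C, M)
  if (any(vals != as.integer(vals)) || any(vals <= 0))
    stop("h, w, C, M must be positive integers")
  hw <- h * w
  list(omega_msa = 4 * hw * C^2 + 2 * hw^2 * C,
       omega_wmsa = 4 * hw * C^2 + 2 * M^2 * hw * C)
}
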