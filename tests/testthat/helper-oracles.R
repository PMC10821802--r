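# Shared fixtures and independent reference implementations used to check
# the package's vectorized code paths.

rand_image <- function(h, w = h, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# A left-dark / right-bright vertical step image.
step_image <- function(h, w = h) {
  img <- array(0, c(h, w, 3))
  img[, (w %/% 2 + 1):w, ] <- 1
  img
}

# Micro architecture used wherever full Swin-T geometry is not the point.
micro_config <- function(num_classes = 3L)
  swin_config(image_size = 8L, patch_size = 2L, embed_dim = 4L,
              window_size = 2L, depths = c(2L, 2L), heads = c(2L, 2L),
              num_classes = num_classes)

small_config <- function(num_classes = 2L)
  swin_config(image_size = 32L, patch_size = 4L, embed_dim = 16L,
              window_size = 4L, depths = c(2L, 2L), heads = c(2L, 4L),
              num_classes = num_classes)

# Nested-loop replicate-padded 3x3 cross-correlation (reference for the
# vectorized shift-and-add implementation).
oracle_xcorr3 <- function(gray, kernel) {
  h <- nrow(gray); w <- ncol(gray)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      acc <- acc + kernel[di + 2, dj + 2] * gray[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Dense scaled-dot-product attention restricted to one window, computed
# token by token with explicit loops (relative position bias included).
oracle_window_attention <- function(xw, p, heads, M) {
  m2 <- nrow(xw); D <- ncol(xw); d <- D / heads
  stopifnot(m2 == M * M)
  qkv <- matrix(0, m2, 3 * D)
  for (i in seq_len(m2))
    qkv[i, ] <- as.vector(xw[i, ] %*% p$qkv$W) + p$qkv$b
  out <- matrix(0, m2, D)
  rpos <- cbind(rep(seq_len(M) - 1, each = M), rep(seq_len(M) - 1, M))
  for (h in seq_len(heads)) {
    cols <- (h - 1) * d + seq_len(d)
    for (i in seq_len(m2)) {
      logits <- numeric(m2)
      for (j in seq_len(m2)) {
        dr <- rpos[i, 1] - rpos[j, 1] + M - 1
        dc <- rpos[i, 2] - rpos[j, 2] + M - 1
        bias <- p$rpb[dr * (2 * M - 1) + dc + 1, h]
        logits[j] <- sum(qkv[i, cols] * qkv[j, D + cols]) / sqrt(d) + bias
      }
      wts <- exp(logits - max(logits))
      wts <- wts / sum(wts)
      for (j in seq_len(m2))
        out[i, cols] <- out[i, cols] + wts[j] * qkv[j, 2 * D + cols]
    }
  }
  t(apply(out, 1, function(r) as.vector(r %*% p$proj$W) + p$proj$b))
}

# Literal layer norm: normalize each token, then scale and shift.
oracle_layernorm <- function(x, g, b) {
  t(apply(x, 1, function(r) {
    mu <- mean(r)
    (r - mu) / sqrt(mean((r - mu)^2) + 1e-5) * g + b
  }))
}

oracle_mlp <- function(x, p) {
  h <- sweep(x %*% p$fc1$W, 2, p$fc1$b, "+")
  h <- h * pnorm(h)
  sweep(h %*% p$fc2$W, 2, p$fc2$b, "+")
}

# Brute-force per-class recomputation of macro metrics from a confusion
# matrix, looping over classes and samples.
oracle_macro_metrics <- function(m) {
  K <- nrow(m); total <- sum(m)
  prec <- rec <- f1 <- acc <- numeric(K)
  for (k in seq_len(K)) {
    tp <- m[k, k]
    fp <- sum(m[, k]) - tp
    fn <- sum(m[k, ]) - tp
    tn <- total - tp - fp - fn
    acc[k] <- (tp + tn) / total
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  c(accuracy = mean(acc), precision = mean(prec), recall = mean(rec),
    f1 = mean(f1))
}

random_confusion <- function(K, seed) {
  set.seed(seed)
  matrix(rpois(K * K, 3) + diag(rpois(K, 10)), K, K)
}

digest_file <- function(f) unname(tools::md5sum(f))

# Two-class, 8+8-image synthetic training set shared by the smoke tests.
make_smoke_dataset <- function(dir, seed = 11, size = 32) {
  man <- data.frame(
    label_index = 1:2,
    label_name = c("Apple healthy", "Apple_Scab serious"),
    train_count = c(8L, 8L), test_count = c(2L, 2L))
  class(man) <- c("class_manifest", "data.frame")
  generate_dataset(man, scale = 1, out_dir = dir, seed = seed, size = size)
  man
}
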