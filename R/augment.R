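# Train-time augmentation: random horizontal flip, color jitter, Mixup and
# CutMix. All operations act on H x W x 3 arrays in [0, 1] and on soft
# labels; augmentation runs on the raw image before the Sobel edge channel
# is derived, so both channels always see geometrically consistent inputs.

#' Augmentation policy
#'
#' @param flip_prob probability of a horizontal mirror.
#' @param brightness,contrast,saturation half-widths of the multiplicative
#'   jitter ranges (factor drawn uniformly from `[max(0, 1 - r), 1 + r]`).
#' @param hue maximal absolute hue rotation (fraction of the hue circle).
#' @param mixup_alpha,cutmix_alpha Beta-distribution shape parameters of
#'   the mixing coefficient; set to `NA` to disable the technique.
#' @return object of class `aug_policy`.
#' @export
aug_policy <- function(flip_prob = 0.5, brightness = 0.4, contrast = 0.4,
                       saturation = 0.4, hue = 0.1, mixup_alpha = 0.8,
                       cutmix_alpha = 1.0) {
  stopifnot(flip_prob >= 0, flip_prob <= 1,
            brightness >= 0, contrast >= 0, saturation >= 0, hue >= 0)
  if (!is.na(mixup_alpha)) stopifnot(mixup_alpha > 0)
  if (!is.na(cutmix_alpha)) stopifnot(cutmix_alpha > 0)
  structure(list(flip_prob = flip_prob, brightness = brightness,
                 contrast = contrast, saturation = saturation, hue = hue,
                 mixup_alpha = mixup_alpha, cutmix_alpha = cutmix_alpha),
            class = "aug_policy")
}

#' Horizontal mirror flip
#'
#' @param image H x W x 3 array.
#' @param prob flip probability (1 forces the flip, 0 is the identity).
#' @return possibly mirrored image; labels are unaffected by flips.
#' @export
random_flip <- function(image, prob = 0.5) {
  if (prob > 0 && stats::runif(1) < prob) flip_horizontal(image) else image
}

flip_horizontal <- function(image) image[, dim(image)[2]:1, , drop = FALSE]

#' Color jitter
#'
#' Perturbs brightness, contrast, saturation and hue by independently
#' drawn random factors within the policy ranges, then clips to `[0, 1]`.
#' With all ranges zero this is the identity on in-range images.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param policy an [aug_policy()].
#' @param factors optional list overriding the drawn factors
#'   (`brightness`, `contrast`, `saturation` multiplicative; `hue`
#'   additive), for deterministic use.
#' @return jittered image, clipped to `[0, 1]`.
#' @export
color_jitter <- function(image, policy = aug_policy(), factors = NULL) {
  f <- function(r) if (r > 0) stats::runif(1, max(0, 1 - r), 1 + r) else 1
  if (is.null(factors)) {
    bf <- f(policy$brightness); cf <- f(policy$contrast)
    sf <- f(policy$saturation)
    hf <- if (policy$hue > 0) stats::runif(1, -policy$hue, policy$hue)
          else 0
  } else {
    bf <- factors$brightness %||% 1; cf <- factors$contrast %||% 1
    sf <- factors$saturation %||% 1; hf <- factors$hue %||% 0
  }
  out <- image * bf
  gray_mean <- mean(to_grayscale(clip01(out)))
  out <- (out - gray_mean) * cf + gray_mean
  g <- to_grayscale(clip01(out))
  for (ch in 1:3) out[, , ch] <- g + sf * (out[, , ch] - g)
  out <- clip01(out)
  if (hf != 0) out <- shift_hue(out, hf)
  clip01(out)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rotate hue by `shift` (fraction of the circle) through HSV space.
shift_hue <- function(image, shift) {
  d <- dim(image)
  rgb <- matrix(aperm(image, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] + shift) %% 1
  out <- hsv_to_rgb(hsv)
  aperm(array(out, dim = c(3, d[1], d[2])), c(2, 3, 1))
}

# Vectorized HSV -> RGB (h, s, v rows in [0, 1]).
hsv_to_rgb <- function(hsv) {
  h <- hsv[1, ] * 6; s <- hsv[2, ]; v <- hsv[3, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

#' Mixup of two labeled samples
#'
#' Convex combination of two images and their soft labels with a
#' coefficient `lambda ~ Beta(alpha, alpha)` (overridable for testing).
#'
#' @param sample_a,sample_b lists with `image` (same shape) and `label`
#'   (same-length simplex vectors).
#' @param alpha Beta shape parameter.
#' @param lambda optional fixed coefficient in `[0, 1]`.
#' @return list with mixed `image`, `label` and the realized `lam`.
#' @export
mixup <- function(sample_a, sample_b, alpha = 0.8, lambda = NULL) {
  check_pair(sample_a, sample_b)
  lam <- if (is.null(lambda)) stats::rbeta(1, alpha, alpha) else lambda
  list(image = lam * sample_a$image + (1 - lam) * sample_b$image,
       label = lam * sample_a$label + (1 - lam) * sample_b$label,
       lam = lam)
}

#' CutMix of two labeled samples
#'
#' Cuts a rectangle of expected area `(1 - lambda) * H * W` from image B
#' and pastes it into image A; labels are mixed with the exact visible-area
#' fraction `lam_adjusted = 1 - box_area / (H * W)` after border clipping.
#'
#' @inheritParams mixup
#' @param alpha Beta shape parameter (default 1 = uniform lambda).
#' @return list with mixed `image`, `label`, realized `lam` (adjusted) and
#'   the pasted `box` (`r1, r2, c1, c2`, or NULL when the box is empty).
#' @export
cutmix <- function(sample_a, sample_b, alpha = 1.0, lambda = NULL) {
  check_pair(sample_a, sample_b)
  lam <- if (is.null(lambda)) stats::rbeta(1, alpha, alpha) else lambda
  d <- dim(sample_a$image); H <- d[1]; W <- d[2]
  cut_ratio <- sqrt(1 - lam)
  bh <- as.integer(round(H * cut_ratio)); bw <- as.integer(round(W * cut_ratio))
  cr <- sample.int(H, 1); cc <- sample.int(W, 1)
  r1 <- max(1L, cr - bh %/% 2L); r2 <- min(H, cr + (bh - 1L) %/% 2L)
  c1 <- max(1L, cc - bw %/% 2L); c2 <- min(W, cc + (bw - 1L) %/% 2L)
  img <- sample_a$image
  box <- NULL
  area <- 0
  if (bh > 0L && bw > 0L) {
    img[r1:r2, c1:c2, ] <- sample_b$image[r1:r2, c1:c2, ]
    area <- (r2 - r1 + 1) * (c2 - c1 + 1)
    box <- c(r1 = r1, r2 = r2, c1 = c1, c2 = c2)
  }
  lam_adj <- 1 - area / (H * W)
  list(image = img,
       label = lam_adj * sample_a$label + (1 - lam_adj) * sample_b$label,
       lam = lam_adj, box = box)
}

check_pair <- function(a, b) {
  if (!identical(dim(a$image), dim(b$image)))
    stop("images must have identical shapes")
  if (length(a$label) != length(b$label))
    stop("labels must have identical lengths")
  invisible(TRUE)
}

#' Augment a training batch
#'
#' Applies per-image flip and color jitter, then at most one of Mixup or
#' CutMix to the whole batch (chosen with equal probability when both are
#' enabled), pairing each sample with a random partner from the same
#' batch. Consumes the R random stream; seed beforehand for reproducible
#' batches.
#'
#' @param batch list of samples, each `list(image, label)` with simplex
#'   labels.
#' @param policy an [aug_policy()].
#' @return augmented batch of the same length.
#' @export
augment_batch <- function(batch, policy = aug_policy()) {
  batch <- lapply(batch, function(s) {
    s$image <- color_jitter(random_flip(s$image, policy$flip_prob), policy)
    s
  })
  modes <- c(if (!is.na(policy$mixup_alpha)) "mixup",
             if (!is.na(policy$cutmix_alpha)) "cutmix")
  if (length(modes) == 0L || length(batch) < 2L) return(batch)
  mode <- if (length(modes) == 1L) modes else
    modes[sample.int(2L, 1L)]
  partner <- sample(seq_along(batch))
  lapply(seq_along(batch), function(i) {
    if (mode == "mixup")
      mixup(batch[[i]], batch[[partner[i]]], policy$mixup_alpha)
    else
      cutmix(batch[[i]], batch[[partner[i]]], policy$cutmix_alpha)
  })
}
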