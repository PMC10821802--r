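#' Trainable Sobel kernel pair
#'
#' Returns the pair of 3x3 gradient kernels that initializes the edge
#' channel's convolution layer. `gx` responds to horizontal intensity
#' changes, `gy` to vertical ones, and at initialization `gx` is exactly
#' the transpose of `gy`. The kernels are plain numeric matrices; when
#' `trainable = TRUE` they are registered as model parameters and updated
#' by back-propagation, after which the transpose relation need not hold.
#'
#' @param trainable logical; whether the kernels participate in training.
#' @return An object of class `sobel_kernels`: list with 3x3 matrices
#'   `gx`, `gy` and flag `trainable`.
#' @export
sobel_kernels <- function(trainable = TRUE) {
  gx <- matrix(c(
    +1, 0, -1,
    +2, 0, -2,
    +1, 0, -1
  ), nrow = 3, byrow = TRUE)
  gy <- matrix(c(
    +1, +2, +1,
     0,  0,  0,
    -1, -2, -1
  ), nrow = 3, byrow = TRUE)
  structure(list(gx = gx, gy = gy, trainable = isTRUE(trainable)),
            class = "sobel_kernels")
}

#' Convert an RGB image to grayscale
#'
#' ITU-R BT.601 luminance: `0.299 R + 0.587 G + 0.114 B`. The weights sum
#' to one, so neutral grays map to themselves.
#'
#' @param image H x W x 3 numeric array, values in `[0, 1]`.
#' @return H x W numeric matrix.
#' @export
to_grayscale <- function(image) {
  check_image(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Replicate-padded 2-D cross-correlation with a 3x3 kernel, same-size output.
# Implemented as a sum of 9 shifted copies of the image; the shifted copy for
# kernel offset (di, dj) is also what the kernel-gradient accumulation needs,
# so both directions share this helper.
shifted_image <- function(gray, di, dj) {
  h <- nrow(gray); w <- ncol(gray)
  ri <- pmin(pmax(seq_len(h) + di, 1L), h)
  cj <- pmin(pmax(seq_len(w) + dj, 1L), w)
  gray[ri, cj, drop = FALSE]
}

cross_correlate3 <- function(gray, kernel) {
  out <- matrix(0, nrow(gray), ncol(gray))
  for (di in -1:1) for (dj in -1:1) {
    out <- out + kernel[di + 2L, dj + 2L] * shifted_image(gray, di, dj)
  }
  out
}

#' Sobel response maps
#'
#' Cross-correlates a grayscale image with both kernels (the convention of
#' deep-learning convolution layers: no kernel flip). Border pixels use
#' replicate padding so the response maps keep the input size and a
#' constant image yields exactly zero response.
#'
#' @param gray H x W numeric matrix, at least 3x3.
#' @param kernels a [sobel_kernels()] object.
#' @return list with matrices `gx_map`, `gy_map`.
#' @export
sobel_response <- function(gray, kernels = sobel_kernels()) {
  stopifnot(is.matrix(gray))
  if (nrow(gray) < 3L || ncol(gray) < 3L)
    stop("image must be at least 3x3 to convolve with a 3x3 kernel")
  list(gx_map = cross_correlate3(gray, kernels$gx),
       gy_map = cross_correlate3(gray, kernels$gy))
}

#' Gradient-magnitude edge map
#'
#' Per-pixel Euclidean magnitude `sqrt(gx^2 + gy^2)` of the two response
#' maps, rescaled to `[0, 1]` by the per-image maximum (an all-zero map
#' stays zero).
#'
#' @param gx_map,gy_map equally sized numeric matrices.
#' @return numeric matrix in `[0, 1]`.
#' @export
edge_magnitude <- function(gx_map, gy_map) {
  if (!identical(dim(gx_map), dim(gy_map)))
    stop("response maps must have identical dimensions")
  mag <- sqrt(gx_map^2 + gy_map^2)
  m <- max(mag)
  if (m > EDGE_EPS) mag <- mag / m else mag[] <- 0
  mag
}

# Magnitudes at or below this are accumulated floating-point residue of the
# shift-and-add convolution on flat regions, not edges; rescaling by such a
# maximum would blow noise up to 1.
EDGE_EPS <- 1e-9

#' Build the edge-channel input image
#'
#' The lower channel of the two-channel model does not see the raw image:
#' it sees a 3-channel image whose channels all equal the rescaled Sobel
#' gradient magnitude of the grayscale image. Replicating the single
#' magnitude map into three channels lets both channels share one
#' patch-embedding geometry. The whole map is differentiable with respect
#' to the kernel elements (see [edge_input_grad()]), which is what makes
#' the Sobel layer trainable.
#'
#' @param image H x W x 3 numeric array in `[0, 1]`.
#' @param kernels a [sobel_kernels()] object.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
make_edge_input <- function(image, kernels = sobel_kernels()) {
  fwd <- edge_input_forward(image, kernels)
  fwd$edge
}

# Forward pass retaining everything the backward pass needs.
edge_input_forward <- function(image, kernels) {
  gray <- to_grayscale(image)
  resp <- sobel_response(gray, kernels)
  mag <- sqrt(resp$gx_map^2 + resp$gy_map^2)
  m <- max(mag)
  if (m <= EDGE_EPS) m <- 0
  imax <- which.max(mag)            # subgradient through the running max
  norm <- if (m > 0) mag / m else mag * 0
  edge <- array(norm, dim = c(dim(norm), 3L))
  list(edge = edge, gray = gray, gx_map = resp$gx_map, gy_map = resp$gy_map,
       mag = mag, m = m, imax = imax)
}

# d(loss)/d(gx), d(loss)/d(gy) given d(loss)/d(edge input).
# The per-image max is treated as locally constant in its argmax pixel
# (subgradient of the max); pixels with zero magnitude get zero gradient.
edge_input_backward <- function(d_edge, fwd) {
  d_norm <- d_edge[, , 1] + d_edge[, , 2] + d_edge[, , 3]
  if (fwd$m > 0) {
    d_mag <- d_norm / fwd$m
    d_mag[fwd$imax] <- d_mag[fwd$imax] -
      sum(d_norm * fwd$mag) / fwd$m^2
  } else {
    d_mag <- d_norm * 0
  }
  nz <- fwd$mag > EDGE_EPS
  d_gx_map <- matrix(0, nrow(fwd$mag), ncol(fwd$mag))
  d_gy_map <- d_gx_map
  d_gx_map[nz] <- d_mag[nz] * fwd$gx_map[nz] / fwd$mag[nz]
  d_gy_map[nz] <- d_mag[nz] * fwd$gy_map[nz] / fwd$mag[nz]
  d_gx <- matrix(0, 3, 3)
  d_gy <- matrix(0, 3, 3)
  for (di in -1:1) for (dj in -1:1) {
    sh <- shifted_image(fwd$gray, di, dj)
    d_gx[di + 2L, dj + 2L] <- sum(d_gx_map * sh)
    d_gy[di + 2L, dj + 2L] <- sum(d_gy_map * sh)
  }
  list(gx = d_gx, gy = d_gy)
}

#' Gradient of a weighted sum of the edge input with respect to the kernels
#'
#' Computes `d(sum(weights * make_edge_input(image, kernels))) / d(kernel)`
#' analytically. Exposed so the trainability of the Sobel layer can be
#' audited directly (e.g. against finite differences).
#'
#' @param image H x W x 3 numeric array.
#' @param kernels a [sobel_kernels()] object.
#' @param weights H x W x 3 numeric array of scalarization weights.
#' @return list of 3x3 matrices `gx`, `gy`.
#' @export
edge_input_grad <- function(image, kernels, weights) {
  fwd <- edge_input_forward(image, kernels)
  stopifnot(identical(dim(weights), dim(fwd$edge)))
  edge_input_backward(weights, fwd)
}

check_image <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3L))
    stop("image must be an H x W x C array")
  if (dim(image)[3] != 3L)
    stop("image must have exactly 3 channels, got ", dim(image)[3])
  if (!all(is.finite(image))) stop("image contains non-finite values")
  invisible(TRUE)
}
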