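# Deterministic synthetic leaf images. The generator emulates the
# structure of the ligneous leaf-disease benchmark: 22 imbalanced classes
# (healthy leaves plus general/serious severity grades of each disease),
# lesions dispersed across the whole blade rather than confined to one
# spot. It makes no attempt at photorealism; its job is to carry a
# learnable, class-specific signal through the full pipeline.

#' The 22-class image distribution of the benchmark dataset
#'
#' Per-class training and testing image counts of the ligneous-leaf
#' subset used throughout (total 11,603 training and 1,668 testing
#' images over 22 classes).
#'
#' @return data.frame of class `class_manifest` with columns
#'   `label_index`, `label_name`, `train_count`, `test_count`.
#' @export
table2_manifest <- function() {
  m <- data.frame(
    label_index = 1:22,
    label_name = c(
      "Apple healthy", "Apple_Scab general", "Apple_Scab serious",
      "Apple Frogeye Spot", "Cedar Apple Rust general",
      "Cedar Apple Rust serious", "Cherry healthy",
      "Cherry_Powdery Mildew general", "Cherry_Powdery Mildew serious",
      "Grape healthy", "Grape Black Rot Fungus general",
      "Grape Black Rot Fungus serious",
      "Grape Black Measles Fungus general",
      "Grape Black Measles Fungus serious",
      "Grape Leaf Blight Fungus general",
      "Grape Leaf Blight Fungus serious", "Citrus healthy",
      "Citrus Greening June general", "Citrus Greening June serious",
      "Peach healthy", "Peach_Bacterial Spot general",
      "Peach_Bacterial Spot serious"),
    train_count = c(1185L, 211L, 152L, 427L, 142L, 40L, 598L, 116L, 110L,
                    294L, 381L, 462L, 503L, 419L, 61L, 630L, 367L, 1828L,
                    1799L, 251L, 857L, 770L),
    test_count = c(169L, 30L, 22L, 61L, 20L, 6L, 85L, 12L, 18L, 42L, 54L,
                   66L, 74L, 59L, 9L, 90L, 52L, 269L, 262L, 36L, 122L,
                   110L),
    stringsAsFactors = FALSE
  )
  class(m) <- c("class_manifest", "data.frame")
  m
}

#' Rendering parameters of one synthetic leaf class
#'
#' @param name class label.
#' @param hue blade hue center (fraction of the hue circle; greens sit
#'   near 0.25-0.38).
#' @param lesion_rate expected lesion count (Poisson); 0 for healthy
#'   classes.
#' @param lesion_size mean lesion radius as a fraction of image size.
#' @param lesion_hue lesion hue (browns near 0.05-0.10).
#' @param severity `"healthy"`, `"general"` or `"serious"`; serious
#'   classes carry a higher lesion density than their general pair.
#' @return object of class `leaf_class_spec`.
#' @export
leaf_class_spec <- function(name, hue, lesion_rate, lesion_size = 0.045,
                            lesion_hue = 0.07,
                            severity = c("general", "serious",
                                         "healthy")) {
  severity <- match.arg(severity)
  stopifnot(hue >= 0, hue <= 1, lesion_rate >= 0, lesion_size > 0)
  if (severity == "healthy" && lesion_rate != 0)
    stop("healthy specs must have lesion_rate 0")
  structure(list(name = name, hue = hue, lesion_rate = lesion_rate,
                 lesion_size = lesion_size, lesion_hue = lesion_hue,
                 severity = severity),
            class = "leaf_class_spec")
}

#' Default rendering specs for a class manifest
#'
#' Derives one distinct `leaf_class_spec` per manifest row: the plant
#' determines the base hue, the severity suffix the lesion density
#' (healthy 0, general 10, serious 28 expected lesions), and a small
#' per-class hue offset keeps all parameter tuples distinct.
#'
#' @param manifest a `class_manifest` (default [table2_manifest()]).
#' @return named list of `leaf_class_spec`s.
#' @export
default_class_specs <- function(manifest = table2_manifest()) {
  base_hues <- c(Apple = 0.30, Cedar = 0.32, Cherry = 0.36, Grape = 0.26,
                 Citrus = 0.24, Peach = 0.38)
  specs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    nm <- manifest$label_name[i]
    plant <- strsplit(gsub("_", " ", nm), " ")[[1]][1]
    sev <- if (grepl("healthy", nm)) "healthy"
           else if (grepl("serious", nm)) "serious" else "general"
    rate <- switch(sev, healthy = 0, general = 10, serious = 28)
    hue <- unname(base_hues[plant]) + 0.012 * ((i - 1) %% 6)
    specs[[i]] <- leaf_class_spec(nm, hue = hue, lesion_rate = rate,
                                  lesion_hue = 0.05 + 0.004 * (i %% 5),
                                  severity = sev)
  }
  names(specs) <- manifest$label_name
  specs
}

# Run code under a private, restored RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render one synthetic leaf image
#'
#' Draws a textured soil-colored background, an elliptical leaf blade in
#' the class hue with smooth value texture, and (for diseased specs)
#' lesions placed by a seeded point process spread over the whole blade.
#' Bit-identical for identical `(spec, size, seed)`.
#'
#' @param spec a [leaf_class_spec()].
#' @param size image side length in pixels (>= 32).
#' @param seed integer seed.
#' @return `size x size x 3` array in `[0, 1]` with attribute
#'   `lesion_mask` (logical matrix of lesion-core pixels).
#' @export
generate_leaf_image <- function(spec, size = 224L, seed = 1L) {
  if (!inherits(spec, "leaf_class_spec")) stop("invalid class spec")
  if (size < 32L) stop("size must be at least 32")
  with_local_seed(seed, {
    n <- as.integer(size)
    xs <- (seq_len(n) - 0.5) / n
    xm <- matrix(xs, n, n, byrow = TRUE)   # column coordinate
    ym <- matrix(xs, n, n)                 # row coordinate
    # background: brownish soil with smooth waves and fine grain
    wave <- 0.04 * sin(2 * pi * (stats::runif(1, 1, 3) * xm +
                                   stats::runif(1))) +
            0.04 * sin(2 * pi * (stats::runif(1, 1, 3) * ym +
                                   stats::runif(1)))
    grain <- matrix(stats::rnorm(n * n, 0, 0.015), n, n)
    img <- array(0, dim = c(n, n, 3L))
    bg <- c(0.36, 0.28, 0.18)
    for (ch in 1:3) img[, , ch] <- bg[ch] + wave + grain
    # blade: rotated ellipse
    theta <- stats::runif(1, 0, pi)
    a <- stats::runif(1, 0.36, 0.44); b <- stats::runif(1, 0.24, 0.30)
    cx <- stats::runif(1, 0.46, 0.54); cy <- stats::runif(1, 0.46, 0.54)
    dx <- xm - cx; dy <- ym - cy
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    r2 <- u^2 + v^2
    blade <- r2 <= 1
    hue <- (spec$hue + stats::runif(1, -0.01, 0.01)) %% 1
    val <- 0.45 + 0.18 * (1 - r2) + 0.05 * sin(12 * u) * cos(9 * v) +
      matrix(stats::rnorm(n * n, 0, 0.02), n, n)
    sat <- 0.55 + 0.1 * (1 - r2)
    leaf_rgb <- hsv_to_rgb(rbind(rep(hue, sum(blade)),
                                 clip01(sat[blade]), clip01(val[blade])))
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[blade] <- leaf_rgb[ch, ]
      img[, , ch] <- pl
    }
    # lesions: seeded point process over the whole blade interior
    lesion_mask <- matrix(FALSE, n, n)
    k <- if (spec$lesion_rate > 0) stats::rpois(1, spec$lesion_rate) else 0L
    if (k > 0) {
      # uniform in the unit disc, mapped through the ellipse transform so
      # centroids disperse across the entire blade
      rr <- sqrt(stats::runif(k)) * 0.92
      ph <- stats::runif(k, 0, 2 * pi)
      lu <- rr * cos(ph); lv <- rr * sin(ph)
      lx <- cx + a * lu * cos(theta) - b * lv * sin(theta)
      ly <- cy + a * lu * sin(theta) + b * lv * cos(theta)
      lrad <- stats::runif(k, 0.55, 1.45) * spec$lesion_size
      lhue <- (spec$lesion_hue + stats::runif(k, -0.01, 0.01)) %% 1
      for (j in seq_len(k)) {
        d2 <- ((xm - lx[j])^2 + (ym - ly[j])^2) / lrad[j]^2
        alpha <- pmax(0, 1 - d2) * blade
        core <- (d2 <= 1) & blade
        lesion_mask <- lesion_mask | core
        lcol <- hsv_to_rgb(matrix(c(lhue[j], 0.75, 0.35), 3, 1))
        for (ch in 1:3)
          img[, , ch] <- img[, , ch] * (1 - alpha) + lcol[ch] * alpha
      }
    }
    img <- clip01(img)
    attr(img, "lesion_mask") <- lesion_mask
    img
  })
}

sanitize_class_name <- function(x) gsub("[^A-Za-z0-9_]+", "_", x)

derive_seed <- function(seed, ...) {
  v <- c(seed, ...)
  s <- 0
  for (x in v) s <- (s * 1000003 + as.numeric(x)) %% (2^31 - 1)
  as.integer(s)
}

#' Write a synthetic image-folder dataset
#'
#' Renders `ceiling(scale * count)` images per manifest class and split
#' into `<out_dir>/<split>/<class>/<class>_<index>.png`, plus a
#' machine-readable `manifest.csv` (columns label_index, label_name,
#' split, count). Fully seeded: the same arguments reproduce identical
#' file bytes.
#'
#' @param manifest a `class_manifest`; default [table2_manifest()].
#' @param scale fraction of the manifest counts to render (0 < scale <= 1).
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed; per-image seeds are derived from it.
#' @param size image side length in pixels.
#' @param specs per-class rendering specs; default
#'   [default_class_specs()].
#' @return (invisibly) data.frame of written counts per class and split.
#' @export
generate_dataset <- function(manifest = table2_manifest(), scale = 0.01,
                             out_dir, seed = 1L, size = 224L,
                             specs = default_class_specs(manifest)) {
  stopifnot(scale > 0, scale <= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  rows <- list()
  for (split in c("train", "test")) {
    split_id <- if (split == "train") 1L else 2L
    for (i in seq_len(nrow(manifest))) {
      cnt_col <- paste0(split, "_count")
      n_img <- ceiling(scale * manifest[[cnt_col]][i])
      cls <- sanitize_class_name(manifest$label_name[i])
      cdir <- file.path(out_dir, split, cls)
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      # test files continue the per-class numbering after the training
      # files, so the two trees never share a file name
      offset <- if (split == "test")
        ceiling(scale * manifest$train_count[i]) else 0L
      for (j in seq_len(n_img)) {
        img <- generate_leaf_image(specs[[i]], size = size,
                                   seed = derive_seed(seed, split_id, i, j))
        png::writePNG(img, file.path(cdir, sprintf("%s_%04d.png", cls,
                                                   j + offset)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        label_index = manifest$label_index[i],
        label_name = manifest$label_name[i], split = split,
        count = n_img, stringsAsFactors = FALSE)
    }
  }
  written <- do.call(rbind, rows)
  utils::write.csv(written, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(written)
}
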