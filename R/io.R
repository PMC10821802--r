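# Image and dataset I/O. Datasets live on disk in image-folder layout:
# <root>/<class_name>/<image>.png (one directory per class).

#' Read an image file as an H x W x 3 array in [0, 1]
#'
#' Grayscale images are replicated to 3 channels; an alpha channel is
#' dropped. When `size` is given the image is resized (bilinear) to
#' `size x size`.
#'
#' @param path PNG file path.
#' @param size optional target side length in pixels.
#' @return H x W x 3 numeric array.
#' @export
load_image <- function(path, size = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (!is.null(size) && (dim(img)[1] != size || dim(img)[2] != size))
    img <- resize_image(img, size)
  img
}

#' Bilinear resize to a square
#'
#' @param image H x W x 3 array; `size` target side length.
#' @return size x size x 3 array clipped to `[0, 1]`.
#' @export
resize_image <- function(image, size) {
  ebi <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(ebi, w = size, h = size)
  clip01(aperm(as.array(out), c(2, 1, 3)))
}

#' Index an image-folder dataset
#'
#' @param root directory containing one subdirectory per class.
#' @return data.frame with columns `path`, `class_name`, `label` (1-based
#'   index in lexicographic class order), one row per image, in stable
#'   lexicographic order.
#' @export
read_image_folder <- function(root) {
  if (!dir.exists(root)) stop("dataset directory not found: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("no class directories under ", root)
  rows <- lapply(seq_along(classes), function(i) {
    files <- sort(list.files(file.path(root, classes[i]),
                             pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) return(NULL)
    data.frame(path = files, class_name = classes[i], label = i,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "class_names") <- classes
  out
}

# Load one dataset row as a model-ready sample.
load_sample <- function(row, num_classes, size) {
  label <- numeric(num_classes)
  label[row$label] <- 1
  list(image = load_image(row$path, size = size), label = label,
       class_index = row$label)
}

#' Write per-image class probabilities
#'
#' @param probs n x K matrix of probabilities; `paths` image paths;
#'   `class_names` column labels.
#' @param file output path; format chosen by extension (`.csv` or
#'   `.json`).
#' @export
write_predictions <- function(probs, paths, class_names, file) {
  colnames(probs) <- class_names
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(
      lapply(seq_along(paths), function(i)
        list(path = paths[i], probabilities = as.list(probs[i, ]))),
      file, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(path = paths, probs,
                                check.names = FALSE),
                     file, row.names = FALSE)
  }
  invisible(file)
}
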