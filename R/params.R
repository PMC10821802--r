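# Parameters and gradients are nested named lists whose leaves are numeric
# vectors/matrices/arrays. These helpers give the optimizer and the
# checkpoint code a flat dot-separated view of that tree.

is_param_leaf <- function(x) is.numeric(x)

#' Flatten a nested parameter tree
#'
#' @param params nested named list of numeric leaves.
#' @param prefix name prefix for recursion.
#' @return named list of numeric leaves, names joined with `.`.
#' @export
flatten_params <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    x <- params[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is_param_leaf(x)) out[[key]] <- x
    else if (is.list(x)) out <- c(out, flatten_params(x, key))
  }
  out
}

#' Rebuild a nested tree from a flat named list
#'
#' @param flat named list as produced by [flatten_params()].
#' @return nested list.
#' @export
unflatten_params <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- assign_path(out, path, flat[[key]])
  }
  out
}

assign_path <- function(tree, path, value) {
  if (length(path) == 1L) {
    tree[[path]] <- value
    return(tree)
  }
  head <- path[[1]]
  if (is.null(tree[[head]])) tree[[head]] <- list()
  tree[[head]] <- assign_path(tree[[head]], path[-1L], value)
  tree
}

# Elementwise combination of two same-shaped trees (b may be NULL).
nested_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  if (is_param_leaf(a)) return(a + b)
  for (nm in names(b)) a[[nm]] <- nested_add(a[[nm]], b[[nm]])
  a
}

nested_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is_param_leaf(a)) return(a * s)
  lapply(a, nested_scale, s = s)
}

# Zero tree with the same shape as params.
nested_zeros <- function(params) nested_scale(params, 0)

n_parameters <- function(params) {
  sum(vapply(flatten_params(params), length, integer(1)))
}
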