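#' Construct the two-channel classifier
#'
#' Builds the full model: an upper transformer channel for the raw image,
#' an independent lower channel (no weight sharing) for the Sobel edge
#' image, the trainable Sobel kernel pair, and a fully-connected softmax
#' head over the concatenated pooled features (upper first, width
#' `2 * feature_dim`).
#'
#' @param config a [swin_config()].
#' @param seed optional integer; when given, parameter initialization is
#'   reproducible.
#' @param sobel_trainable whether the Sobel kernels receive gradient
#'   updates (`FALSE` reproduces a fixed classical Sobel operator).
#' @return object of class `dual_model`: list with `config`, `params`
#'   (`upper`, `lower`, `sobel`, `head`) and `sobel_trainable`.
#' @export
dual_model <- function(config = swin_config(), seed = NULL,
                       sobel_trainable = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  k <- sobel_kernels(trainable = sobel_trainable)
  params <- list(
    upper = init_channel_params(config),
    lower = init_channel_params(config),
    sobel = list(gx = k$gx, gy = k$gy),
    head = list(W = trunc_normal(2L * config$feature_dim,
                                 config$num_classes),
                b = numeric(config$num_classes))
  )
  structure(list(config = config, params = params,
                 sobel_trainable = isTRUE(sobel_trainable)),
            class = "dual_model")
}

#' @export
print.dual_model <- function(x, ...) {
  cf <- x$config
  cat("Two-channel shifted-window transformer\n")
  cat("  input:", cf$image_size, "x", cf$image_size, "x 3,",
      "patches", cf$patch_size, "x", cf$patch_size, "\n")
  cat("  stages:", paste(cf$depths, collapse = "/"),
      "blocks, dims", paste(cf$stage_dims, collapse = "/"), "\n")
  cat("  classes:", cf$num_classes,
      " parameters:", n_parameters(x$params), "\n")
  invisible(x)
}

#' Forward pass of the two-channel model
#'
#' The upper channel consumes the raw image; the lower channel consumes
#' [make_edge_input()] of the same image. Pooled features are concatenated
#' (upper first) and mapped by the fully-connected head to class logits,
#' normalized by softmax.
#'
#' @param image H x W x 3 numeric array in `[0, 1]`.
#' @param model a [dual_model()].
#' @param want_cache keep intermediate state for back-propagation.
#' @param training enable train-time stochasticity (stochastic depth).
#' @return object of class `prediction`: list with `probabilities`
#'   (simplex over classes), `logits`, `features` (fused pre-head vector)
#'   and, when requested, `cache`.
#' @export
dual_forward <- function(image, model, want_cache = FALSE,
                         training = FALSE) {
  p <- model$params
  kern <- structure(list(gx = p$sobel$gx, gy = p$sobel$gy,
                         trainable = model$sobel_trainable),
                    class = "sobel_kernels")
  edge_fwd <- edge_input_forward(image, kern)
  up <- channel_forward(image, model$config, p$upper, want_cache, training)
  lo <- channel_forward(edge_fwd$edge, model$config, p$lower, want_cache,
                        training)
  features <- c(up$feature, lo$feature)
  logits <- as.vector(features %*% p$head$W) + p$head$b
  probabilities <- exp(log_softmax_vec(logits))
  cache <- if (want_cache)
    list(up = up$cache, lo = lo$cache, edge_fwd = edge_fwd,
         features = features, probabilities = probabilities)
  structure(list(probabilities = probabilities, logits = logits,
                 features = features, stage_grids = up$stage_grids,
                 cache = cache),
            class = "prediction")
}

#' Cross-entropy classification loss
#'
#' `-sum(target_k * log p_k)` over classes. The target is either a hard
#' class index (1-based) or a soft label vector on the probability simplex
#' (as produced by Mixup/CutMix).
#'
#' @param pred a `prediction` from [dual_forward()], or any list with a
#'   `logits` element.
#' @param target integer class index or numeric simplex vector.
#' @return non-negative scalar loss.
#' @export
classification_loss <- function(pred, target) {
  logp <- log_softmax_vec(pred$logits)
  t <- as_soft_target(target, length(logp))
  -sum(t * logp)
}

as_soft_target <- function(target, K) {
  if (length(target) == 1L && is.numeric(target)) {
    idx <- as.integer(target)
    if (idx < 1L || idx > K) stop("class index ", idx, " outside 1..", K)
    t <- numeric(K); t[idx] <- 1
    return(t)
  }
  if (length(target) != K)
    stop("soft target length ", length(target), " != ", K, " classes")
  if (any(target < -1e-9) || abs(sum(target) - 1) > 1e-6)
    stop("soft target is not on the probability simplex")
  pmax(target, 0)
}

# Loss + full gradient of one example. Returns list(loss, grads) with grads
# shaped like model$params (sobel grads zeroed when kernels are frozen).
dual_loss_backward <- function(image, model, target, training = FALSE) {
  pred <- dual_forward(image, model, want_cache = TRUE, training = training)
  K <- model$config$num_classes
  t <- as_soft_target(target, K)
  loss <- -sum(t * log_softmax_vec(pred$logits))
  d_logits <- pred$probabilities - t
  feats <- pred$cache$features
  d_head_W <- outer(feats, d_logits)
  d_features <- as.vector(model$params$head$W %*% d_logits)
  Fd <- model$config$feature_dim
  ub <- channel_backward(d_features[seq_len(Fd)], pred$cache$up)
  lb <- channel_backward(d_features[Fd + seq_len(Fd)], pred$cache$lo)
  sob <- edge_input_backward(lb$d_image, pred$cache$edge_fwd)
  if (!model$sobel_trainable) sob <- list(gx = sob$gx * 0, gy = sob$gy * 0)
  list(loss = loss, prediction = pred$probabilities,
       grads = list(upper = ub$grads, lower = lb$grads,
                    sobel = sob,
                    head = list(W = d_head_W, b = d_logits)))
}

# ---- pretrained backbone import ----------------------------------------

#' Mapping between package parameter paths and Swin checkpoint names
#'
#' One row per backbone parameter of a single channel: `ours` is the
#' dot-separated path inside a channel parameter tree, `theirs` the
#' flat name used by publicly distributed Swin-T ImageNet checkpoints
#' (e.g. `layers.0.blocks.1.attn.qkv.weight`). Linear weights in such
#' archives are stored (out, in) and are transposed on import; the patch
#' embedding is stored as a (C, 3, P, P) convolution kernel and is
#' flattened to our (P^2*3, C) matrix (channel-major patch ordering).
#' The classification head and the Sobel kernels are never imported.
#'
#' @param config a [swin_config()].
#' @return data.frame with columns `ours`, `theirs`, `kind`.
#' @export
swin_name_map <- function(config) {
  rows <- list(
    c("patch_embed.proj.W", "patch_embed.proj.weight", "conv"),
    c("patch_embed.proj.b", "patch_embed.proj.bias", "vector"),
    c("patch_embed.norm.g", "patch_embed.norm.weight", "vector"),
    c("patch_embed.norm.b", "patch_embed.norm.bias", "vector"),
    c("norm.g", "norm.weight", "vector"),
    c("norm.b", "norm.bias", "vector")
  )
  for (s in seq_len(config$n_stages)) {
    so <- paste0("stages.stage", s); st <- paste0("layers.", s - 1L)
    for (i in seq_len(config$depths[s])) {
      bo <- paste0(so, ".blocks.block", i)
      bt <- paste0(st, ".blocks.", i - 1L)
      rows <- c(rows, list(
        c(paste0(bo, ".norm1.g"), paste0(bt, ".norm1.weight"), "vector"),
        c(paste0(bo, ".norm1.b"), paste0(bt, ".norm1.bias"), "vector"),
        c(paste0(bo, ".attn.qkv.W"), paste0(bt, ".attn.qkv.weight"), "linear"),
        c(paste0(bo, ".attn.qkv.b"), paste0(bt, ".attn.qkv.bias"), "vector"),
        c(paste0(bo, ".attn.proj.W"), paste0(bt, ".attn.proj.weight"), "linear"),
        c(paste0(bo, ".attn.proj.b"), paste0(bt, ".attn.proj.bias"), "vector"),
        c(paste0(bo, ".attn.rpb"),
          paste0(bt, ".attn.relative_position_bias_table"), "matrix"),
        c(paste0(bo, ".norm2.g"), paste0(bt, ".norm2.weight"), "vector"),
        c(paste0(bo, ".norm2.b"), paste0(bt, ".norm2.bias"), "vector"),
        c(paste0(bo, ".mlp.fc1.W"), paste0(bt, ".mlp.fc1.weight"), "linear"),
        c(paste0(bo, ".mlp.fc1.b"), paste0(bt, ".mlp.fc1.bias"), "vector"),
        c(paste0(bo, ".mlp.fc2.W"), paste0(bt, ".mlp.fc2.weight"), "linear"),
        c(paste0(bo, ".mlp.fc2.b"), paste0(bt, ".mlp.fc2.bias"), "vector")
      ))
    }
    if (s < config$n_stages) {
      rows <- c(rows, list(
        c(paste0(so, ".merge.norm.g"), paste0(st, ".downsample.norm.weight"),
          "vector"),
        c(paste0(so, ".merge.norm.b"), paste0(st, ".downsample.norm.bias"),
          "vector"),
        c(paste0(so, ".merge.reduce.W"),
          paste0(st, ".downsample.reduction.weight"), "linear")
      ))
    }
  }
  m <- do.call(rbind, rows)
  data.frame(ours = m[, 1], theirs = m[, 2], kind = m[, 3],
             stringsAsFactors = FALSE)
}

convert_imported <- function(value, kind) {
  switch(kind,
    vector = as.numeric(value),
    matrix = as.matrix(value),
    linear = t(as.matrix(value)),  # archives store (out, in)
    conv = {
      # (C_out, C_in, P, P) array -> (P^2*3, C_out), channel-major rows
      dm <- dim(value)
      W <- matrix(0, dm[2] * dm[3] * dm[4], dm[1])
      for (o in seq_len(dm[1]))
        W[, o] <- as.vector(aperm(value[o, , , , drop = FALSE][1, , , ],
                                  c(3, 2, 1)))
      W
    },
    stop("unknown parameter kind ", kind))
}

#' Load pretrained backbone weights into one or both channels
#'
#' Replaces backbone parameters of the selected channel(s) with values
#' from a flat named archive keyed by the public Swin checkpoint names
#' (see [swin_name_map()]). The classification head and the Sobel kernels
#' are never taken from the archive: the head stays freshly initialized
#' and the kernels keep their classical initialization. Archive entries
#' with no mapped name are skipped; a mapped entry whose shape disagrees
#' with the model is a hard error naming the parameter.
#'
#' @param model a [dual_model()].
#' @param archive named list of numeric arrays (checkpoint naming).
#' @param channel `"upper"`, `"lower"` or `"both"`.
#' @return the model with weights replaced; attribute `"report"` carries
#'   data.frame of loaded and skipped names.
#' @export
load_pretrained <- function(model, archive, channel = c("both", "upper",
                                                        "lower")) {
  channel <- match.arg(channel)
  map <- swin_name_map(model$config)
  targets <- if (channel == "both") c("upper", "lower") else channel
  loaded <- character(); skipped <- setdiff(names(archive), map$theirs)
  for (ch in targets) {
    flat <- flatten_params(model$params[[ch]])
    for (r in seq_len(nrow(map))) {
      theirs <- map$theirs[r]
      if (!theirs %in% names(archive)) next
      v <- convert_imported(archive[[theirs]], map$kind[r])
      ours <- map$ours[r]
      cur <- flat[[ours]]
      if (is.null(cur)) stop("unknown parameter path ", ours)
      if (!identical(dim_or_len(cur), dim_or_len(v)))
        stop("shape mismatch importing '", theirs, "' into '", ch, ".",
             ours, "': archive ", paste(dim_or_len(v), collapse = "x"),
             " vs model ", paste(dim_or_len(cur), collapse = "x"))
      flat[[ours]] <- v
      loaded <- c(loaded, paste0(ch, ".", ours))
    }
    model$params[[ch]] <- unflatten_params(flat)
  }
  attr(model, "report") <- list(loaded = loaded, skipped = skipped)
  model
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- checkpoints --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a flat named-parameter archive plus a metadata block
#' (configuration, class names, epoch, validation accuracy), serialized
#' with [saveRDS()].
#'
#' @param model a [dual_model()]; `path` file path.
#' @param class_names optional character vector of class labels.
#' @param epoch,val_accuracy optional training provenance.
#' @export
save_checkpoint <- function(model, path, class_names = NULL, epoch = NA,
                            val_accuracy = NA) {
  saveRDS(list(
    params = flatten_params(model$params),
    config = unclass(model$config),
    sobel_trainable = model$sobel_trainable,
    class_names = class_names, epoch = epoch, val_accuracy = val_accuracy
  ), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a `dual_model` with attributes `class_names`, `epoch`,
#'   `val_accuracy`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  config <- do.call(swin_config, ck$config[c(
    "image_size", "patch_size", "embed_dim", "window_size", "depths",
    "heads", "num_classes", "mlp_ratio", "drop_path_rate", "use_rpb")])
  model <- structure(list(config = config,
                          params = unflatten_params(ck$params),
                          sobel_trainable = ck$sobel_trainable),
                     class = "dual_model")
  attr(model, "class_names") <- ck$class_names
  attr(model, "epoch") <- ck$epoch
  attr(model, "val_accuracy") <- ck$val_accuracy
  model
}
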