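#' Training configuration
#'
#' Defaults follow the study's training recipe: mini-batches of 8, Adam at
#' learning rate 1e-4, 100 epochs, 10-fold cross-validation. Moment decay
#' and epsilon are the Adam standards.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training set.
#' @param folds number of cross-validation folds.
#' @param seed integer seed governing shuffling, augmentation and
#'   stochastic depth.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @param clip_norm global gradient-norm ceiling (the standard
#'   stabilizer for windowed-attention backbones); `Inf` disables
#'   clipping.
#' @param policy an [aug_policy()], or NULL to train without augmentation.
#' @param checkpoint_path optional path; when given together with a
#'   validation set, the best-validation-accuracy model is saved there
#'   (ties resolved toward the later epoch).
#' @param verbose print per-epoch log lines.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 1e-4,
                         epochs = 100L, folds = 10L, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         clip_norm = 5, policy = NULL,
                         checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(batch_size >= 1, learning_rate >= 0, epochs >= 1, folds >= 2,
            clip_norm > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 folds = as.integer(folds), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 clip_norm = clip_norm, policy = policy,
                 checkpoint_path = checkpoint_path,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads_flat, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads_flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

#' Train the two-channel model
#'
#' Mini-batch Adam on the (hard or soft-label) cross-entropy loss, with
#' optional per-batch augmentation, per-epoch logging and optional
#' best-by-validation checkpointing. Fully seeded: the same seed, data
#' and configuration reproduce the loss trajectory bit-identically (with
#' stochastic depth disabled).
#'
#' @param model a [dual_model()].
#' @param data training manifest from [read_image_folder()], or a dataset
#'   directory.
#' @param config a [train_config()].
#' @param val_data optional validation manifest or directory.
#' @return list with the trained `model`, `log` (data.frame of epoch,
#'   loss, train_accuracy, val_accuracy), `final_train_accuracy`
#'   (argmax accuracy on the un-augmented training set) and
#'   `best_epoch`.
#' @export
train <- function(model, data, config = train_config(), val_data = NULL) {
  manifest <- as_manifest(data)
  if (nrow(manifest) == 0L) stop("empty training dataset")
  val_manifest <- if (!is.null(val_data)) as_manifest(val_data)
  cf <- model$config
  set.seed(config$seed)
  samples <- lapply(seq_len(nrow(manifest)), function(i)
    load_sample(manifest[i, ], cf$num_classes, cf$image_size))
  flat <- flatten_params(model$params)
  opt <- adam_init(flat)
  n <- length(samples)
  log_rows <- vector("list", config$epochs)
  best_val <- -Inf; best_epoch <- NA
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0; hits <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      ids <- perm[start:min(start + config$batch_size - 1L, n)]
      batch <- samples[ids]
      if (!is.null(config$policy)) batch <- augment_batch(batch,
                                                          config$policy)
      grads <- NULL; bloss <- 0
      for (s in batch) {
        res <- dual_loss_backward(s$image, model, s$label,
                                  training = TRUE)
        if (!is.finite(res$loss))
          stop("non-finite loss at epoch ", epoch, "; aborting")
        grads <- nested_add(grads, res$grads)
        bloss <- bloss + res$loss
        hits <- hits + (which.max(res$prediction) ==
                          which.max(s$label))
      }
      grads <- nested_scale(grads, 1 / length(batch))
      gf <- flatten_params(grads)
      gn <- sqrt(sum(vapply(gf, function(g) sum(g^2), numeric(1))))
      if (is.finite(config$clip_norm) && gn > config$clip_norm)
        gf <- lapply(gf, function(g) g * config$clip_norm / gn)
      upd <- adam_step(flat, gf, opt,
                       config$learning_rate, config$beta1, config$beta2,
                       config$eps)
      flat <- upd$flat; opt <- upd$state
      model$params <- unflatten_params(flat)
      epoch_loss <- epoch_loss + bloss
    }
    val_acc <- NA_real_
    if (!is.null(val_manifest)) {
      vc <- evaluate(model, val_manifest)
      val_acc <- sum(diag(unclass(vc))) / sum(vc)
      if (val_acc >= best_val) {  # ties -> latest epoch
        best_val <- val_acc; best_epoch <- epoch
        if (!is.null(config$checkpoint_path))
          save_checkpoint(model, config$checkpoint_path,
                          class_names = attr(manifest, "class_names"),
                          epoch = epoch, val_accuracy = val_acc)
      }
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = epoch_loss / n, train_accuracy = hits / n,
      val_accuracy = val_acc)
    if (config$verbose)
      cat(sprintf("epoch %3d  loss %.4f  train_acc %.3f  val_acc %s\n",
                  epoch, epoch_loss / n, hits / n,
                  ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
  }
  counts <- evaluate(model, manifest)
  list(model = model, log = do.call(rbind, log_rows),
       final_train_accuracy = sum(diag(unclass(counts))) / sum(counts),
       best_epoch = best_epoch)
}

as_manifest <- function(data) {
  if (is.character(data)) read_image_folder(data) else data
}

#' Evaluate a model on a dataset
#'
#' Argmax-of-probabilities prediction per image (ties broken toward the
#' lowest class index), accumulated into a confusion matrix. Unreadable
#' images are skipped with a warning and recorded in the `skipped`
#' attribute.
#'
#' @param model a [dual_model()].
#' @param data manifest or dataset directory.
#' @return `confusion_counts` matrix (rows true, columns predicted).
#' @export
evaluate <- function(model, data) {
  manifest <- as_manifest(data)
  cf <- model$config
  true <- integer(); pred <- integer(); skipped <- character()
  for (i in seq_len(nrow(manifest))) {
    img <- tryCatch(load_image(manifest$path[i], size = cf$image_size),
                    error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable image: ", manifest$path[i])
      skipped <- c(skipped, manifest$path[i])
      next
    }
    p <- dual_forward(img, model)$probabilities
    true <- c(true, manifest$label[i])
    pred <- c(pred, which.max(p))
  }
  counts <- confusion_counts(true, pred, cf$num_classes)
  attr(counts, "skipped") <- skipped
  counts
}

#' Export fused pre-head features
#'
#' Writes one row per image: path, true label, and the concatenated
#' pooled feature vector of both channels (width `2 * feature_dim`),
#' for downstream embedding/visualization by a standard
#' dimensionality-reduction tool.
#'
#' @param model a [dual_model()].
#' @param data manifest or dataset directory.
#' @param file output CSV path; NULL returns the data.frame only.
#' @return (invisibly) the feature data.frame.
#' @export
export_features <- function(model, data, file = NULL) {
  manifest <- as_manifest(data)
  cf <- model$config
  feats <- matrix(0, nrow(manifest), 2L * cf$feature_dim)
  for (i in seq_len(nrow(manifest))) {
    img <- load_image(manifest$path[i], size = cf$image_size)
    feats[i, ] <- dual_forward(img, model)$features
  }
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  out <- data.frame(path = manifest$path, label = manifest$label, feats,
                    check.names = FALSE)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
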