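#' Confusion counts from labels
#'
#' @param true,pred integer class indices (1-based).
#' @param num_classes number of classes K.
#' @return K x K integer matrix of class `confusion_counts`; rows are true
#'   classes, columns predicted classes.
#' @export
confusion_counts <- function(true, pred, num_classes) {
  stopifnot(length(true) == length(pred))
  m <- matrix(0L, num_classes, num_classes)
  for (i in seq_along(true)) {
    m[true[i], pred[i]] <- m[true[i], pred[i]] + 1L
  }
  structure(m, class = c("confusion_counts", "matrix"))
}

#' Per-class one-vs-rest tallies
#'
#' For each class k: TP = diagonal entry, FP = column sum minus TP,
#' FN = row sum minus TP, TN = remainder.
#'
#' @param counts confusion matrix (rows = true, columns = predicted).
#' @return data.frame with columns class, TP, TN, FP, FN.
#' @export
ovr_counts <- function(counts) {
  m <- unclass(counts)
  total <- sum(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  data.frame(class = seq_len(nrow(m)), TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Accuracy, precision, recall and F1 from binary tallies
#'
#' Vectorized over classes: accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 the harmonic mean of precision
#' and recall. Undefined ratios (0/0) are reported as 0 and flagged.
#'
#' @param tp,tn,fp,fn non-negative counts (recycled together).
#' @return data.frame with the four metrics and an `undefined` flag.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- safe(2 * precision * recall, precision + recall)
  data.frame(
    accuracy = safe(tp + tn, tp + tn + fp + fn),
    precision = precision, recall = recall, f1 = f1,
    undefined = (tp + fp == 0) | (tp + fn == 0)
  )
}

#' Evaluation report from a confusion matrix
#'
#' Per-class one-vs-rest metrics plus macro averages (uniform mean over
#' classes, the headline numbers for imbalanced data) and micro averages
#' (pooled counts; for single-label classification micro precision,
#' recall and F1 all equal the overall accuracy, the trace of the matrix
#' over its total).
#'
#' @param counts a `confusion_counts` matrix.
#' @return object of class `metrics_report`: list with `overall_accuracy`,
#'   `macro`, `micro`, `per_class` and `n`.
#' @export
compute_metrics <- function(counts) {
  m <- unclass(counts)
  if (sum(m) == 0) stop("empty confusion matrix")
  o <- ovr_counts(m)
  pc <- cbind(o, metrics_from_counts(o$TP, o$TN, o$FP, o$FN))
  macro <- c(accuracy = mean(pc$accuracy), precision = mean(pc$precision),
             recall = mean(pc$recall), f1 = mean(pc$f1))
  acc <- sum(diag(m)) / sum(m)
  micro <- c(accuracy = acc, precision = acc, recall = acc, f1 = acc)
  structure(list(overall_accuracy = acc, macro = macro, micro = micro,
                 per_class = pc, n = sum(m)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  overall accuracy = %.4f\n", x$n,
              x$overall_accuracy))
  cat(sprintf("macro: precision %.4f  recall %.4f  F1 %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("micro: precision %.4f  recall %.4f  F1 %.4f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"]))
  invisible(x)
}

#' Stratified k-fold split
#'
#' Partitions sample ids into k folds so that per-class counts across
#' folds differ by at most one. Classes with fewer than k samples trigger
#' a warning and are spread best-effort. Bit-identical under a fixed seed.
#'
#' @param labels integer or factor class label per sample.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of k elements, each `list(train_ids, val_ids)` (indices
#'   into `labels`); folds are disjoint and cover all samples.
#' @export
kfold_split <- function(labels, k = 10L, seed = 1L) {
  stopifnot(k >= 2L)
  labels <- as.integer(as.factor(labels))
  set.seed(seed)
  fold_of <- integer(length(labels))
  offset <- 0L
  for (cl in sort(unique(labels))) {
    ids <- which(labels == cl)
    if (length(ids) < k)
      warning("class ", cl, " has ", length(ids), " samples for ", k,
              " folds; stratification is best-effort")
    ids <- ids[sample.int(length(ids))]
    # deal round-robin, rotating the starting fold between classes so
    # small classes do not pile into fold 1
    fold_of[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
    offset <- (offset + length(ids)) %% k
  }
  lapply(seq_len(k), function(f)
    list(train_ids = which(fold_of != f), val_ids = which(fold_of == f)))
}
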