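#' Confusion matrix from labels
#'
#' @param y_true,y_pred Integer class ids in `0:(n_classes-1)`.
#' @param n_classes Number of classes.
#' @return An `n_classes x n_classes` integer matrix, rows = true class,
#'   columns = predicted class, with class `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length", call. = FALSE)
  }
  if (any(c(y_true, y_pred) < 0) || any(c(y_true, y_pred) >= n_classes)) {
    stop("labels outside [0, n_classes)", call. = FALSE)
  }
  lv <- 0:(n_classes - 1)
  cm <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  m <- matrix(as.integer(cm), n_classes, n_classes,
              dimnames = list(true = lv, predicted = lv))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Per-class precision, recall and F1
#'
#' `TP_i` is the diagonal entry, `FP_i` the rest of column i, `FN_i` the rest
#' of row i. A zero denominator yields 0 (with a message), not `NaN`.
#'
#' @param cm Confusion matrix (rows = true, columns = predicted).
#' @return A tibble with columns `class`, `precision`, `recall`, `f1`.
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    z <- den == 0
    if (any(z)) message("zero denominator in ", what, " for class(es) ",
                        paste(which(z) - 1, collapse = ", "), "; reporting 0")
    out <- numeric(length(num))
    out[!z] <- num[!z] / den[!z]
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  tibble::tibble(class = seq_len(nrow(cm)) - 1L, precision = precision,
                 recall = recall, f1 = f1)
}

#' Macro-averaged metrics and average accuracy
#'
#' Unweighted means of the per-class metrics; the average accuracy (AAC) is
#' the mean of per-class recalls `n_ii / n_i`.
#'
#' @param per_class Tibble from [per_class_metrics()].
#' @param cm The confusion matrix the per-class table came from.
#' @return One-row tibble with `precision`, `recall`, `f1`, `aac` and overall
#'   `accuracy`.
#' @export
macro_metrics <- function(per_class, cm) {
  cm <- unclass(cm)
  rs <- rowSums(cm)
  aac <- mean(ifelse(rs > 0, diag(cm) / rs, 0))
  tibble::tibble(precision = mean(per_class$precision),
                 recall = mean(per_class$recall),
                 f1 = mean(per_class$f1),
                 aac = aac,
                 accuracy = sum(diag(cm)) / max(sum(cm), 1))
}

#' Full classification report
#'
#' @param y_true,y_pred Integer class ids.
#' @param n_classes Number of classes.
#' @return List of class `classification_report` with `confusion`,
#'   `per_class` and `macro`.
#' @export
classification_report <- function(y_true, y_pred, n_classes) {
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  pc <- per_class_metrics(cm)
  structure(list(confusion = cm, per_class = pc,
                 macro = macro_metrics(pc, cm)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x$confusion))
  cat("\nPer-class metrics:\n")
  print(x$per_class)
  cat("\nMacro:\n")
  print(x$macro)
  invisible(x)
}

#' Stratified k-fold evaluation harness
#'
#' Splits a manifest into `k` stratified folds; each fold serves as the
#' validation set exactly once while `train_fn` trains on the remainder and
#' returns the best validation accuracy it observed.
#'
#' @param manifest Data frame with a `class_id` column.
#' @param k Number of folds.
#' @param train_fn Function `(train_manifest, val_manifest, fold) -> accuracy`.
#' @param seed RNG seed controlling the fold assignment.
#' @return List of class `kfold_result` with a per-fold tibble `folds` and
#'   `mean_accuracy`.
#' @export
kfold_evaluate <- function(manifest, k = 10L, train_fn, seed = NULL) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  counts <- table(manifest$class_id)
  if (any(counts < k)) {
    stop("every class needs at least k records", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  fold <- integer(nrow(manifest))
  for (cl in names(counts)) {
    idx <- which(manifest$class_id == as.integer(cl))
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  acc <- vapply(seq_len(k), function(f) {
    train_fn(manifest[fold != f, , drop = FALSE],
             manifest[fold == f, , drop = FALSE], f)
  }, numeric(1))
  structure(list(folds = tibble::tibble(fold = seq_len(k), accuracy = acc),
                 mean_accuracy = mean(acc), assignments = fold),
            class = "kfold_result")
}

#' @export
print.kfold_result <- function(x, ...) {
  print(x$folds)
  cat("Mean accuracy:", format(x$mean_accuracy, digits = 4), "\n")
  invisible(x)
}
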