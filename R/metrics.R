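#' Confusion-matrix metrics for binary CKD prediction
#'
#' Counts TP/TN/FP/FN treating CKD (label 1) as the positive class and
#' derives accuracy, precision, recall, and F1. When a denominator is zero
#' the corresponding metric is defined as 0 (not NaN) so comparison tables
#' stay total.
#'
#' @param y_true 0/1 vector of reference labels.
#' @param y_pred 0/1 vector of predicted labels, same length.
#' @param threshold decision threshold recorded alongside the metrics.
#' @return object of class `ckd_metrics`: list with counts `tp`, `tn`,
#'   `fp`, `fn` and reals `accuracy`, `precision`, `recall`, `f1`,
#'   `threshold`.
#' @export
compute_metrics <- function(y_true, y_pred, threshold = 0.5) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("need at least one prediction")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L)))
    stop("inputs must be binary 0/1")
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  div0 <- function(a, b) if (b == 0) 0 else a / b
  precision <- div0(tp, tp + fp)
  recall <- div0(tp, tp + fn)
  f1 <- div0(2 * precision * recall, precision + recall)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / length(y_true),
                 precision = precision, recall = recall, f1 = f1,
                 threshold = threshold),
            class = "ckd_metrics")
}

#' @export
print.ckd_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("TP %d  FN %d  FP %d  TN %d (threshold %.2f)\n",
              x$tp, x$fn, x$fp, x$tn, x$threshold))
  invisible(x)
}

#' Confusion matrix as a labeled 2x2 table
#' @param m a `ckd_metrics`.
#' @return 2x2 matrix, rows = reference, columns = prediction.
#' @export
confusion_matrix <- function(m) {
  matrix(c(m$tn, m$fp, m$fn, m$tp), 2, 2, byrow = TRUE,
         dimnames = list(reference = c("notckd", "ckd"),
                         prediction = c("notckd", "ckd")))
}
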