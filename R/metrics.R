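#' Confusion matrix of true vs predicted labels
#'
#' `counts[i, j]` is the number of frames of true class `i` predicted as
#' class `j`. Rows are true classes, columns predictions.
#'
#' @param true_labels,pred_labels equal-length vectors of 1-based class
#'   indices (or factors over the same levels).
#' @param n_classes number of classes; inferred from factor levels if
#'   omitted.
#' @param class_names optional class names.
#' @return an `sfx_confusion` (integer matrix with dimnames).
#' @export
confusion <- function(true_labels, pred_labels, n_classes = NULL,
                      class_names = NULL) {
  if (is.factor(true_labels)) {
    class_names <- class_names %||% levels(true_labels)
    true_labels <- as.integer(true_labels)
  }
  if (is.factor(pred_labels)) pred_labels <- as.integer(pred_labels)
  stopifnot(length(true_labels) == length(pred_labels))
  n_classes <- n_classes %||% length(class_names) %||%
    max(true_labels, pred_labels)
  if (any(true_labels < 1 | true_labels > n_classes) ||
      any(pred_labels < 1 | pred_labels > n_classes))
    stop("label outside 1..", n_classes)
  class_names <- class_names %||% as.character(seq_len(n_classes))
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = class_names, predicted = class_names))
  for (k in seq_along(true_labels))
    cm[true_labels[k], pred_labels[k]] <- cm[true_labels[k], pred_labels[k]] + 1L
  structure(cm, class = c("sfx_confusion", "matrix", "array"))
}

#' Overall accuracy of a confusion matrix, in percent
#'
#' `100 * trace / total`.
#'
#' @param cm an `sfx_confusion` or plain square count matrix.
#' @return percentage in `[0, 100]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(as.matrix(cm))) / total
}

#' Per-class recall and precision, in percent
#'
#' One-vs-rest per class: `recall_i = 100 * counts[i,i] / rowsum_i`
#' (TP / (TP + FN)) and `precision_j = 100 * counts[j,j] / colsum_j`
#' (TP / (TP + FP)). Classes with no true (recall) or no predicted
#' (precision) instances are flagged `NA` rather than propagating NaN.
#'
#' @param cm an `sfx_confusion` or plain square count matrix.
#' @return named numeric vector of percentages (`NA` where undefined).
#' @export
per_class_recall <- function(cm) {
  cm <- as.matrix(cm)
  rs <- rowSums(cm)
  ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
}

#' @rdname per_class_recall
#' @export
per_class_precision <- function(cm) {
  cm <- as.matrix(cm)
  cs <- colSums(cm)
  ifelse(cs > 0, 100 * diag(cm) / cs, NA_real_)
}

#' Row-normalized 2x2 hit/miss cross-tabulation
#'
#' Cross-tabulates true vs predicted binary labels and normalizes each row
#' to percentages (each row sums to 100 up to rounding). A true class with
#' no instances yields an `NA` row.
#'
#' @param true_binary,pred_binary vectors of `"hit"`/`"miss"` (or factors
#'   over [sfx_binary_classes]).
#' @return 2x2 numeric matrix of row percentages, rows/cols ordered
#'   `hit`, `miss`.
#' @export
hit_miss_table <- function(true_binary, pred_binary) {
  lv <- c("hit", "miss")
  tb <- factor(as.character(true_binary), levels = lv)
  pb <- factor(as.character(pred_binary), levels = lv)
  stopifnot(length(tb) == length(pb), !anyNA(tb), !anyNA(pb))
  counts <- table(true = tb, predicted = pb)
  out <- matrix(NA_real_, 2, 2, dimnames = dimnames(counts))
  for (i in 1:2) {
    rs <- sum(counts[i, ])
    if (rs > 0) out[i, ] <- 100 * counts[i, ] / rs
  }
  out
}

#' Report-style metric table for a confusion matrix
#'
#' Convenience summary: counts with per-class recall appended as a column
#' and per-class precision as a row, percentages rounded half-up to one
#' decimal (raw fractions remain available via the metric functions).
#'
#' @param cm an `sfx_confusion`.
#' @return data.frame in the conventional published layout.
#' @export
metric_table <- function(cm) {
  cmm <- as.matrix(cm)
  rec <- round_half_up(per_class_recall(cm), 1)
  prec <- round_half_up(per_class_precision(cm), 1)
  df <- as.data.frame(cmm)
  df$`Recall (%)` <- rec
  df <- rbind(df, c(as.list(prec), list(`Recall (%)` = NA)))
  rownames(df) <- c(rownames(cmm), "Precision (%)")
  df
}
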