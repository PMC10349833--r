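#' Confusion matrix for binary superpixel classification
#'
#' Melanoma (label 1) is the positive class throughout the package: a false
#' negative is a melanoma superpixel called nevus, the error the pipeline
#' most wants to avoid.
#'
#' @param y_true,y_pred Equal-length vectors of labels in \{0, 1\}.
#' @param positive_class The positive label (default 1 = melanoma).
#' @return An object of class `confusion_matrix`: list with counts `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
#' @examples
#' confusion(c(1, 1, 1, 0, 0), c(1, 0, 1, 1, 0))
confusion <- function(y_true, y_pred, positive_class = 1L) {
  if (length(y_true) != length(y_pred)) {
    stopf("y_true (%d) and y_pred (%d) differ in length",
          length(y_true), length(y_pred))
  }
  if (length(y_true) < 1L) stopf("empty label vectors")
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Accuracy, precision, recall, F1 and MCC from a confusion matrix
#'
#' \deqn{Accuracy = (TP+TN)/(TP+TN+FN+FP)}
#' \deqn{Precision = TP/(TP+FP), \quad Recall = TP/(TP+FN)}
#' \deqn{F1 = 2 \cdot Recall \cdot Precision / (Recall + Precision)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#'
#' A metric whose denominator is zero is reported as 0 and listed in the
#' `undefined` attribute (and the `undefined` column) rather than raising, so
#' batch sweeps over degenerate splits never abort.
#'
#' @param cm A [confusion()] result, or a list with `tp`, `tn`, `fp`, `fn`.
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f1`, `mcc` and a list-column `undefined` naming any flagged metrics;
#'   the same names are attached as the `undefined` attribute.
#' @export
#' @examples
#' compute_metrics(list(tp = 30, tn = 40, fp = 10, fn = 20))
compute_metrics <- function(cm) {
  counts <- as.numeric(c(cm$tp, cm$tn, cm$fp, cm$fn))
  if (any(counts < 0)) stopf("confusion counts must be non-negative")
  if (sum(counts) < 1) stopf("confusion matrix is empty")
  tp <- counts[1]; tn <- counts[2]; fp <- counts[3]; fn <- counts[4]
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den <= 0) {
      undef <<- c(undef, name)
      0
    } else {
      num / den
    }
  }
  accuracy <- safe(tp + tn, tp + tn + fn + fp, "accuracy")
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * recall * precision, recall + precision, "f1")
  mcc <- safe(tp * tn - fp * fn,
              sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)), "mcc")
  out <- tibble::tibble(accuracy = accuracy, precision = precision,
                        recall = recall, f1 = f1, mcc = mcc,
                        undefined = list(undef))
  attr(out, "undefined") <- undef
  out
}

#' Evaluate predicted labels against truth in one call
#'
#' @inheritParams confusion
#' @return A one-row tibble: the [compute_metrics()] columns plus `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
evaluate_predictions <- function(y_true, y_pred, positive_class = 1L) {
  cm <- confusion(y_true, y_pred, positive_class)
  dplyr::bind_cols(compute_metrics(cm),
                   tibble::tibble(tp = cm$tp, tn = cm$tn,
                                  fp = cm$fp, fn = cm$fn))
}
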