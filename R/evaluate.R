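# Binary-classifier evaluation: precision, recall/sensitivity, specificity,
# F-measure and accuracy from confusion counts, plus threshold-sweep ROC and
# precision-recall curves. Malignant is the positive class throughout.

#' Confusion counts
#'
#' @param TP,TN,FP,FN non-negative integers; at least one must be positive.
#'   TP: positives classified positive; TN: negatives classified negative;
#'   FP: negatives classified positive; FN: positives classified negative.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  stopifnot(all(v >= 0), sum(v) >= 1)
  structure(as.list(as.integer(v)), names = names(v),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Evaluation metrics from confusion counts
#'
#' Computes precision `TP/(TP+FP)`, recall/sensitivity `TP/(TP+FN)`,
#' specificity `TN/(FP+TN)`, F-measure (harmonic mean of precision and
#' recall) and accuracy `(TP+TN)/(TP+TN+FP+FN)`, all unrounded. A metric
#' whose denominator is zero is returned as `NA` and named in the `flags`
#' field (never silently reported as 0).
#'
#' @param counts a [confusion_counts()] object.
#' @return An object of class `metrics_report`: a list with the five metrics
#'   and a character vector `flags` of undefined metrics.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  flags <- character(0)
  div <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); return(NA_real_) }
    num / den
  }
  precision <- div(counts$TP, counts$TP + counts$FP, "precision")
  recall <- div(counts$TP, counts$TP + counts$FN, "recall_sensitivity")
  specificity <- div(counts$TN, counts$FP + counts$TN, "specificity")
  f <- if (is.na(precision) || is.na(recall)) {
    flags <- c(flags, "f_measure"); NA_real_
  } else if (precision + recall == 0) {
    flags <- c(flags, "f_measure"); NA_real_
  } else 2 * precision * recall / (precision + recall)
  accuracy <- (counts$TP + counts$TN) /
    (counts$TP + counts$TN + counts$FP + counts$FN)
  structure(list(precision = precision, recall_sensitivity = recall,
                 specificity = specificity, f_measure = f,
                 accuracy = accuracy, flags = unique(flags),
                 counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4L, ...) {
  cat(sprintf("precision %.*f  recall/sensitivity %.*f  specificity %.*f  F-measure %.*f  accuracy %.*f\n",
              digits, x$precision, digits, x$recall_sensitivity,
              digits, x$specificity, digits, x$f_measure,
              digits, x$accuracy))
  if (length(x$flags)) cat("undefined:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Metrics rounded the way published comparison tables print them
#'
#' Rounds precision, recall, specificity and accuracy to `digits` decimal
#' places and computes the F-measure from the *already-rounded* precision and
#' recall before rounding it in turn — the convention under which the
#' reference comparison table of k-NN/SVM/CNN runs bundled with this package
#' ([isic_reference_counts()]) is reproduced exactly on all rows.
#'
#' @param counts a [confusion_counts()] object.
#' @param digits decimal places (default 2).
#' @return Named numeric vector `precision`, `recall_sensitivity`,
#'   `specificity`, `f_measure`, `accuracy`.
#' @export
printed_metrics <- function(counts, digits = 2L) {
  m <- metrics(counts)
  p <- round(m$precision, digits)
  r <- round(m$recall_sensitivity, digits)
  f <- if (is.na(p) || is.na(r) || p + r == 0) NA_real_
  else round(2 * p * r / (p + r), digits)
  c(precision = p, recall_sensitivity = r,
    specificity = round(m$specificity, digits), f_measure = f,
    accuracy = round(m$accuracy, digits))
}

#' Published reference confusion counts and printed metrics
#'
#' The six evaluation rounds of the reference melanoma CBR system on
#' ISIC-archive images (k-NN and SVM over hand-crafted features, then the
#' sixteen-layer CNN; first round 300 training / 100 test images, second
#' round 1346 / 450), as printed: confusion counts plus the reported
#' precision, recall (sensitivity), specificity, F-measure and accuracy.
#' These rows serve as exact regression fixtures for [metrics()] /
#' [printed_metrics()].
#'
#' @return Data frame with columns `test`, `TP`, `TN`, `FP`, `FN`,
#'   `precision`, `recall_sensitivity`, `specificity`, `f_measure`,
#'   `accuracy`.
#' @export
isic_reference_counts <- function() {
  data.frame(
    test = c("knn_round1", "svm_round1", "knn_round2", "svm_round2",
             "cnn_round1", "cnn_round2"),
    TP = c(30L, 25L, 124L, 105L, 35L, 164L),
    TN = c(34L, 37L, 178L, 149L, 33L, 175L),
    FP = c(16L, 13L, 47L, 76L, 17L, 50L),
    FN = c(20L, 25L, 101L, 120L, 15L, 61L),
    precision = c(0.65, 0.66, 0.73, 0.58, 0.67, 0.77),
    recall_sensitivity = c(0.60, 0.50, 0.55, 0.47, 0.70, 0.73),
    specificity = c(0.68, 0.74, 0.79, 0.66, 0.66, 0.78),
    f_measure = c(0.62, 0.57, 0.63, 0.52, 0.68, 0.75),
    accuracy = c(0.64, 0.62, 0.67, 0.56, 0.68, 0.75),
    stringsAsFactors = FALSE)
}

#' Tally confusion counts from labels and predictions
#'
#' @param labels true labels (`"benign"`/`"malignant"`).
#' @param predictions predicted labels, same length and coding.
#' @param positive the positive class (default `"malignant"`).
#' @return A [confusion_counts()] object.
#' @export
confusion_from_predictions <- function(labels, predictions,
                                       positive = "malignant") {
  labels <- as.character(labels); predictions <- as.character(predictions)
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  pos <- labels == positive
  ppos <- predictions == positive
  confusion_counts(TP = sum(pos & ppos), TN = sum(!pos & !ppos),
                   FP = sum(!pos & ppos), FN = sum(pos & !ppos))
}

#' ROC and precision-recall curves with trapezoid AUCs
#'
#' Sweeps the decision threshold over every unique score value (plus
#' infinite endpoints), classifying as positive where `score >= threshold`.
#' The ROC curve collects (FPR, TPR) pairs and its AUC is the trapezoid
#' integral, which equals the Mann-Whitney pair statistic with ties at half
#' weight; the PR curve and AUC are analogous over (recall, precision).
#'
#' @param labels true labels (`"benign"`/`"malignant"`).
#' @param scores numeric malignancy scores, larger = more malignant.
#' @param positive the positive class.
#' @return List of class `roc_pr_curves`: `roc` (data frame `threshold`,
#'   `fpr`, `tpr`), `pr` (data frame `threshold`, `recall`, `precision`),
#'   `auc_roc`, `auc_pr`.
#' @export
roc_pr_curves <- function(labels, scores, positive = "malignant") {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(scores))
  pos <- labels == positive
  if (all(pos) || !any(pos)) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  np <- sum(pos); nn <- sum(!pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tp <- vapply(thr, function(t) sum(pos & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!pos & scores >= t), numeric(1))
  tpr <- tp / np
  fpr <- fp / nn
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- ifelse(tp + fp == 0, 1, tp / (tp + fp))
  auc_pr <- sum(diff(tpr) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  structure(list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 pr = data.frame(threshold = thr, recall = tpr,
                                 precision = prec),
                 auc_roc = auc_roc, auc_pr = auc_pr),
            class = "roc_pr_curves")
}

#' @export
print.roc_pr_curves <- function(x, ...) {
  cat(sprintf("<roc_pr_curves> AUC-ROC %.4f, AUC-PR %.4f, %d thresholds\n",
              x$auc_roc, x$auc_pr, nrow(x$roc)))
  invisible(x)
}

#' Plot ROC and precision-recall curves
#'
#' @param x a `roc_pr_curves` object.
#' @param ... passed to [plot()].
#' @export
plot.roc_pr_curves <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "FPR", ylab = "TPR",
       main = sprintf("ROC (AUC %.3f)", x$auc_roc), ...)
  graphics::abline(0, 1, lty = 3)
  plot(x$pr$recall, x$pr$precision, type = "l", xlab = "Recall",
       ylab = "Precision", main = sprintf("PR (AUC %.3f)", x$auc_pr),
       ylim = c(0, 1), ...)
  invisible(x)
}

#' Write a JSON metrics report
#'
#' @param report a `metrics_report`.
#' @param path output JSON path.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(
    list(counts = unclass(report$counts),
         precision = report$precision,
         recall_sensitivity = report$recall_sensitivity,
         specificity = report$specificity,
         f_measure = report$f_measure,
         accuracy = report$accuracy,
         flags = report$flags),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
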