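#' Classification accuracy measures, ROC curves and AUC
#'
#' Performance is summarized from the 2x2 confusion table: the
#' classification error E = (FP+FN)/n, recall (sensitivity)
#' R = TP/(TP+FN), precision P = TP/(TP+FP), the true/false positive
#' rates, specificity, accuracy and Matthews correlation coefficient.
#' ROC curves plot TPR against FPR over the score thresholds and the
#' area under the curve equals the probability that a random positive is
#' ranked above a random negative.
#'
#' @name metrics
NULL

#' Confusion counts from binary decisions
#'
#' @param decisions 0/1 predicted classes.
#' @param labels 0/1 true classes.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(decisions, labels) {
  if (length(decisions) != length(labels))
    stop("decisions and labels differ in length")
  if (length(labels) < 1L) stop("empty input")
  stopifnot(all(decisions %in% c(0L, 1L)), all(labels %in% c(0L, 1L)))
  c(TP = sum(decisions == 1L & labels == 1L),
    FP = sum(decisions == 1L & labels == 0L),
    TN = sum(decisions == 0L & labels == 0L),
    FN = sum(decisions == 0L & labels == 1L))
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Accuracy measures from confusion counts
#'
#' Rates with a zero denominator are reported as `NA` (flagged
#' undefined) rather than coerced to 0, so degenerate splits cannot
#' silently win model selection.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; alternatively pass
#'   the vector returned by [confusion_counts()] as `tp`.
#' @return Named list: `error`, `recall`, `precision`, `tpr`, `fpr`,
#'   `specificity`, `accuracy`, `mcc`.
#' @export
classification_rates <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && length(tp) == 4L) {
    fp <- tp[["FP"]]; tn <- tp[["TN"]]; fn <- tp[["FN"]]; tp <- tp[["TP"]]
  }
  counts <- c(tp, fp, tn, fn)
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  n <- tp + fp + tn + fn
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(error = (fp + fn) / n,
       recall = safe_div(tp, tp + fn),
       precision = safe_div(tp, tp + fp),
       tpr = safe_div(tp, tp + fn),
       fpr = safe_div(fp, fp + tn),
       specificity = safe_div(tn, tn + fp),
       accuracy = (tp + tn) / n,
       mcc = if (mcc_den == 0) NA_real_
             else (tp * tn - fp * fn) / mcc_den)
}

#' ROC curve points
#'
#' Thresholds sweep the distinct score values (a sample is called
#' positive when `score >= threshold`); the curve always contains (0, 0)
#' and (1, 1) and both coordinates are non-decreasing.
#'
#' @param scores Real-valued classifier scores (higher = more positive).
#' @param labels 0/1 true classes; both classes must be present.
#' @return Data frame with columns `fpr`, `tpr`, sorted by `fpr`.
#' @export
roc_points <- function(scores, labels) {
  check_two_classes(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  pts <- vapply(sort(unique(scores), decreasing = TRUE), function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0L) / nneg,
      tpr = sum(pred & labels == 1L) / npos)
  }, numeric(2))
  pts <- cbind(c(0, 0), pts, c(1, 1))
  pts <- t(pts)[!duplicated(t(pts)), , drop = FALSE]
  out <- data.frame(fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

check_two_classes <- function(labels) {
  stopifnot(all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute a ROC/AUC")
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank probability that a random positive
#' scores above a random negative, counting ties as 1/2; this equals the
#' trapezoidal area under [roc_points()].
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  check_two_classes(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Full evaluation of scored predictions
#'
#' @param scores Positive-class scores.
#' @param labels 0/1 true classes (both present).
#' @param decisions 0/1 predicted classes; defaults to `score > 0.5`,
#'   the decision rule of a two-output network whose score is the
#'   normalized positive response (ties go negative).
#' @return An `eval_result`: confusion counts, all rates, ROC points and
#'   AUC.
#' @export
evaluate_predictions <- function(scores, labels, decisions = NULL) {
  if (is.null(decisions)) decisions <- as.integer(scores > 0.5)
  counts <- confusion_counts(decisions, labels)
  structure(c(list(counts = counts),
              classification_rates(counts),
              list(roc = roc_points(scores, labels),
                   auc = auc_score(scores, labels),
                   n = length(labels))),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> n =", x$n, "\n")
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$counts[["TP"]],
              x$counts[["FP"]], x$counts[["TN"]], x$counts[["FN"]]))
  cat(sprintf("  error=%.4f recall=%.4f precision=%.4f auc=%.4f mcc=%.4f\n",
              x$error, x$recall, x$precision, x$auc, x$mcc))
  invisible(x)
}

# One summary row per eval_result, used in report TSVs and averaging.
eval_row <- function(ev) {
  data.frame(n = ev$n, TP = ev$counts[["TP"]], FP = ev$counts[["FP"]],
             TN = ev$counts[["TN"]], FN = ev$counts[["FN"]],
             error = ev$error, recall = ev$recall,
             precision = ev$precision, fpr = ev$fpr,
             specificity = ev$specificity, accuracy = ev$accuracy,
             mcc = ev$mcc, auc = ev$auc)
}
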