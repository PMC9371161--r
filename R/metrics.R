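# Evaluation metrics: confusion counts, sensitivity / specificity /
# accuracy, and trapezoidal ROC AUC.

#' Confusion counts for binary apnea/normal labels
#'
#' @param truth,pred character vectors of `"apnea"` / `"normal"` labels.
#' @param positive positive-class label (default `"apnea"`).
#' @return object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, pred, positive = "apnea") {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d FN=%d TN=%d FP=%d\n", x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

ratio0 <- function(num, den, what) {
  if (den == 0) {
    warnf("%s undefined (zero denominator); returning 0", what)
    return(0)
  }
  num / den
}

#' @rdname confusion
#' @param c a `confusion_counts` object.
#' @export
sensitivity <- function(c) ratio0(c$TP, c$TP + c$FN, "sensitivity")

#' @rdname confusion
#' @export
specificity <- function(c) ratio0(c$TN, c$TN + c$FP, "specificity")

#' @rdname confusion
#' @export
accuracy <- function(c) ratio0(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN,
                               "accuracy")

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC curve swept over all score thresholds
#' (ties grouped), equivalent to the Mann-Whitney U statistic divided by
#' the number of positive-negative pairs. Invariant under strictly
#' increasing transforms of the scores.
#'
#' @param truth character labels.
#' @param scores numeric scores, larger = more apnea-like.
#' @param positive positive-class label.
#' @return AUC in `[0, 1]`; degenerate single-class input returns 0 with a
#'   warning.
#' @export
auc_score <- function(truth, scores, positive = "apnea") {
  pos <- truth == positive
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0) {
    warnf("auc undefined with a single class; returning 0")
    return(0)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- pos[o]
  # group tied scores, walk thresholds from +Inf down
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp_g <- tapply(as.numeric(y), grp, sum)
  fp_g <- tapply(as.numeric(!y), grp, sum)
  tpr <- c(0, cumsum(tp_g) / P)
  fpr <- c(0, cumsum(fp_g) / N)
  sum((fpr[-1] - fpr[-length(fpr)]) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}
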