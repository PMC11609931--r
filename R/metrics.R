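# Evaluation metrics: precision/recall/F1 for the positive (ILD) class,
# Mann-Whitney AUC, ROC points and the 2x2 confusion matrix.

#' Mann-Whitney AUC
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted 1/2; computed from midranks, equivalent to
#' normalising the Mann-Whitney U statistic.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 vector.
#' @return AUC in `[0, 1]`; errors if only one class is present.
#' @export
auc_mann_whitney <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stopf("auc_mann_whitney: AUC undefined, test labels contain a single class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the observed scores and returns the
#' (false-positive rate, true-positive rate) path from (0, 0) to (1, 1);
#' both coordinates are monotone non-decreasing.
#'
#' @inheritParams auc_mann_whitney
#' @return data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- c(0, cumsum(lab == 1) / max(n1, 1))
  fpr <- c(0, cumsum(lab == 0) / max(n0, 1))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Classification metric report
#'
#' Builds the full report from positive-class scores and predicted labels:
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R) for the
#' positive class, Mann-Whitney AUC of the scores, the 2x2 confusion
#' matrix (rows = truth 0/1, columns = prediction 0/1) and ROC points.
#' With a single-class truth vector the AUC is reported as `NA` with a
#' warning; the threshold metrics are still computed.
#'
#' @param scores predicted probability of the positive class.
#' @param predicted 0/1 predicted labels.
#' @param truth 0/1 true labels.
#' @return list of class `metric_report`.
#' @export
metric_report <- function(scores, predicted, truth) {
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  auc <- tryCatch(auc_mann_whitney(scores, truth),
                  error = function(e) { warning(conditionMessage(e)); NA_real_ })
  confusion <- matrix(c(tn, fp, fn, tp), 2L, 2L, byrow = TRUE,
                      dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  structure(list(precision = precision, recall = recall, f1 = f1, auc = auc,
                 confusion = confusion, roc = roc_points(scores, truth),
                 n = length(truth)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report (n = %d)\n", x$n))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  AUC %s\n",
              x$precision, x$recall, x$f1,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  cat("  confusion (rows = truth, cols = prediction):\n")
  print(x$confusion)
  invisible(x)
}
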