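#' Confusion counts with cancer as the positive class
#'
#' @param truth character vector of true classes.
#' @param predicted character vector of predicted classes, same length.
#' @param positive the positive-class label (default `"cancer"`).
#' @return a classed list (`ConfusionCounts`) with `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(truth, predicted, positive = "cancer") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted), length(truth) > 0L)
  pos <- truth == positive
  pre <- predicted == positive
  out <- list(TP = sum(pos & pre), FP = sum(!pos & pre),
              TN = sum(!pos & !pre), FN = sum(pos & !pre))
  class(out) <- "ConfusionCounts"
  out
}

#' Area under the ROC curve from margin scores
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive sample outscores a randomly chosen negative one, with ties
#' counting one half. Computed from midranks, so it handles ties exactly.
#'
#' @param scores numeric scores, larger predicting the positive class.
#' @param labels class labels, same length.
#' @param positive the positive-class label (default `"cancer"`).
#' @return AUROC in \[0, 1\].
#' @export
aurocScore <- function(scores, labels, positive = "cancer") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("undefined-AUROC error: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from confusion counts (and margin scores)
#'
#' Computes the evaluation panel used to judge the diagnostic classifier,
#' with cancer as the positive class: recall (sensitivity) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, balanced accuracy
#' `(recall + specificity)/2`, F1 `2PR/(P+R)`, the Matthews correlation
#' coefficient, and (when scores are supplied) the rank-based AUROC.
#' Percent metrics are reported on the 0-100 scale, MCC on -1..1 and AUROC
#' on 0..1.
#'
#' Conventions on zero denominators (documented, not exceptions): precision
#' is `NA` when nothing is predicted positive; F1 is 0 when precision and
#' recall are both 0; MCC is 0 when any marginal total is 0.
#'
#' @param counts a [confusionCounts()] result (or a list with TP/FP/TN/FN).
#' @param scores optional margin scores for AUROC.
#' @param labels class labels matching `scores`.
#' @param positive positive-class label for the AUROC (default `"cancer"`).
#' @return a classed list (`MetricsRecord`) with `balancedAccuracy`,
#'   `specificity`, `precision`, `recall`, `f1` (percent), `mcc`, `auroc`.
#' @export
computeMetrics <- function(counts, scores = NULL, labels = NULL,
                           positive = "cancer") {
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  n <- TP + FP + TN + FN
  if (n <= 0) stop("input error: empty confusion counts", call. = FALSE)
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  recall <- ratio(TP, TP + FN)
  specificity <- ratio(TN, TN + FP)
  precision <- ratio(TP, TP + FP)
  balacc <- mean(c(recall, specificity), na.rm = TRUE)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom > 0) (TP * TN - FP * FN) / sqrt(denom) else 0
  auroc <- if (!is.null(scores))
    aurocScore(scores, labels, positive) else NA_real_
  out <- list(balancedAccuracy = 100 * balacc,
              specificity = 100 * specificity,
              precision = 100 * precision,
              recall = 100 * recall,
              f1 = 100 * f1,
              mcc = mcc,
              auroc = auroc)
  class(out) <- "MetricsRecord"
  out
}

#' @export
print.MetricsRecord <- function(x, ...) {
  cat(sprintf(
    "Bal.acc %.2f%% | Spec %.2f%% | Prec %s | Recall %.2f%% | F1 %.2f%% | MCC %.2f | AUROC %s\n",
    x$balancedAccuracy, x$specificity,
    if (is.na(x$precision)) "NA" else sprintf("%.2f%%", x$precision),
    x$recall, x$f1, x$mcc,
    if (is.na(x$auroc)) "NA" else sprintf("%.3f", x$auroc)))
  invisible(x)
}

#' One-row data.frame view of a metrics record (Table-style report)
#'
#' @param x a `MetricsRecord`.
#' @param dataset dataset label for the row.
#' @param digits decimals for percent metrics (round-half-even, default 2).
#' @return one-row data.frame mirroring the evaluation-report columns.
#' @export
metricsRow <- function(x, dataset = "dataset", digits = 2) {
  data.frame(dataset = dataset,
             bal_acc = round(x$balancedAccuracy, digits),
             specificity = round(x$specificity, digits),
             precision = round(x$precision, digits),
             recall = round(x$recall, digits),
             f1 = round(x$f1, digits),
             auroc = round(x$auroc, 3),
             mcc = round(x$mcc, 2),
             stringsAsFactors = FALSE)
}
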