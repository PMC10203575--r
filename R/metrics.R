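# Threshold-free and thresholded evaluation of binary classifiers:
# ROC-AUC by the rank (Mann-Whitney) formulation with midranks for ties,
# and the confusion-matrix metrics TPR/FPR/PPV/NPV/recall.

#' ROC-AUC by the rank formulation
#'
#' Equals the Mann-Whitney probability that a random positive outscores a
#' random negative, with ties counted half; equivalently the area under the
#' ROC curve. A value near 0.5 indicates a random classifier.
#'
#' @param labels 0/1 (or logical) class labels.
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)) # 3 of 4 pairs won
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have equal length.")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined with a single class; need both labels present.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' A sample is called positive when `score >= threshold`. Metrics with a
#' zero denominator are reported as `NA` (undefined), never coerced to 0.
#'
#' @param labels 0/1 class labels.
#' @param scores Numeric scores.
#' @param threshold Decision threshold (default 0.5, the sigmoid convention).
#' @return One-row tibble: `threshold`, counts `tp`, `fp`, `tn`, `fn`, and
#'   `tpr`, `fpr`, `ppv`, `npv`, `recall` (`recall` is numerically `tpr`).
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have equal length.")
  }
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(
    threshold = threshold,
    tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = safe_div(tp, tp + fn),
    fpr = safe_div(fp, fp + tn),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    recall = safe_div(tp, tp + fn)
  )
}

#' ROC curve points
#'
#' @param labels 0/1 class labels.
#' @param scores Numeric scores.
#' @return Tibble of `(threshold, tpr, fpr)` over all distinct score cutoffs.
#' @export
roc_points <- function(labels, scores) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  dplyr::bind_rows(lapply(cuts, function(t) {
    confusion_metrics(labels, scores, t)[, c("threshold", "tpr", "fpr")]
  }))
}
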