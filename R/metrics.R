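#' Area under the ROC curve
#'
#' Rank-statistic implementation (Mann-Whitney): ties in the scores
#' contribute 1/2. Equivalent to the fraction of (positive, negative) pairs
#' ranked concordantly.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels, same length.
#' @return AUROC in `[0, 1]`, or `NA` when only one class is present.
#' @export
metric_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Confusion counts at a fixed threshold.
confusion_counts <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  c(tp = sum(pred == 1L & labels == 1L),
    tn = sum(pred == 0L & labels == 0L),
    fp = sum(pred == 1L & labels == 0L),
    fn = sum(pred == 0L & labels == 1L))
}

#' Thresholded classification metrics
#'
#' Standard closed forms on confusion counts. `metric_mcc()` returns 0 by
#' convention when any marginal total is zero (the correlation is undefined
#' there); per-class F1 of an empty class is 0; balanced accuracy is `NA`
#' when a true class is absent.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (not all zero).
#' @return A scalar metric value.
#' @export
metric_mcc <- function(tp, tn, fp, fn) {
  check_counts(tp, tn, fp, fn)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' @rdname metric_mcc
#' @export
metric_macro_f1 <- function(tp, tn, fp, fn) {
  check_counts(tp, tn, fp, fn)
  f1_pos <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  f1_neg <- if (2 * tn + fn + fp == 0) 0 else 2 * tn / (2 * tn + fn + fp)
  (f1_pos + f1_neg) / 2
}

#' @rdname metric_mcc
#' @export
metric_balanced_accuracy <- function(tp, tn, fp, fn) {
  check_counts(tp, tn, fp, fn)
  if (tp + fn == 0 || tn + fp == 0) return(NA_real_)
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

check_counts <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative",
                                       call. = FALSE)
  if (tp + tn + fp + fn == 0) stop("all confusion counts are zero",
                                   call. = FALSE)
  invisible(NULL)
}

# All thresholded metrics plus AUROC for one stratum of (score, label) pairs.
stratum_metrics <- function(scores, labels, threshold = 0.5) {
  cc <- as.list(confusion_counts(scores, labels, threshold))
  data.frame(
    n = length(scores),
    auroc = metric_auroc(scores, labels),
    mcc = do.call(metric_mcc, cc),
    macro_f1 = do.call(metric_macro_f1, cc),
    balanced_accuracy = do.call(metric_balanced_accuracy, cc),
    bce = bce_loss(scores, labels))
}
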