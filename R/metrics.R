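# Threshold rule used everywhere: a probability strictly greater than the
# threshold is called positive; exactly equal is called negative.
classify_probs <- function(probs, threshold = 0.5) {
  as.integer(probs > threshold)
}

roc_auc <- function(y, probs) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = probs,
                                 levels = c(0L, 1L), direction = "<",
                                 quiet = TRUE)))
}

#' Classification metrics at a probability threshold
#'
#' Pools a confusion matrix at the threshold (strictly-greater positive
#' rule) and computes TPR (= recall), TNR, precision, F1 and the
#' threshold-free AUC. With no positives in `y`, precision/recall are
#' undefined: the result carries `degenerate = TRUE` and `NA` values rather
#' than silent zeros. F1 is 0 when precision and recall are both 0.
#'
#' @param probs predicted probabilities in \[0, 1\].
#' @param y binary 0/1 labels.
#' @param threshold probability cut-off (default 0.5).
#' @return a list of class `metrics_summary` with fields `auc`, `tpr`,
#'   `tnr`, `precision`, `recall`, `f1`, `threshold`, `degenerate`.
#' @export
metrics_summary <- function(probs, y, threshold = 0.5) {
  y <- as.integer(y)
  stopifnot(length(probs) == length(y))
  keep <- !is.na(probs)
  probs <- probs[keep]; y <- y[keep]
  pred <- classify_probs(probs, threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  degenerate <- sum(y == 1L) == 0L
  tpr <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  precision <- if (tp + fp > 0L) tp / (tp + fp) else if (degenerate)
    NA_real_ else 0
  recall <- tpr
  f1 <- if (degenerate) NA_real_
        else if (is.na(precision) || precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  structure(list(auc = roc_auc(y, probs), tpr = tpr, tnr = tnr,
                 precision = precision, recall = recall, f1 = f1,
                 threshold = threshold, degenerate = degenerate,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf(
    "AUC %.4f | TPR %.3f | TNR %.3f | precision %.3f | F1 %.3f (cut-off %g)\n",
    x$auc, x$tpr, x$tnr, x$precision, x$f1, x$threshold))
  if (isTRUE(x$degenerate))
    cat("  [degenerate: no positive cases in the evaluated labels]\n")
  invisible(x)
}
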