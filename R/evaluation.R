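#' Student-t confidence interval for a fold-wise mean
#'
#' `mean +/- t_{(1+level)/2, k-1} * sd / sqrt(k)`: the interval for a mean
#' estimated from `k` cross-validation folds, treating the fold values as a
#' sample with standard deviation `sd` (sample SD, `k - 1` denominator).
#'
#' @param mean fold-wise mean.
#' @param sd fold-wise sample standard deviation.
#' @param k number of folds (>= 2).
#' @param level confidence level (default 0.95).
#' @return numeric `c(ci_low, ci_high)`.
#' @examples
#' t_interval(0.8944, 0.0290, 10)  # c(0.8737, 0.9151) to 4 decimals
#' @export
t_interval <- function(mean, sd, k, level = 0.95) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  half <- stats::qt((1 + level) / 2, df = k - 1) * sd / sqrt(k)
  c(ci_low = mean - half, ci_high = mean + half)
}

#' Summarise per-fold AUC values
#'
#' @param fold_aucs numeric vector of per-fold AUCs (NAs dropped).
#' @param level confidence level (default 0.95).
#' @return a list of class `fold_auc_summary`: `fold_aucs`, `mean`, `sd`,
#'   `ci_low`, `ci_high`, `level`, `k`.
#' @export
fold_auc_summary <- function(fold_aucs, level = 0.95) {
  fa <- fold_aucs[!is.na(fold_aucs)]
  if (length(fa) < 2L)
    stop("at least two fold AUCs are required", call. = FALSE)
  m <- mean(fa); s <- stats::sd(fa)
  ci <- t_interval(m, s, length(fa), level)
  structure(list(fold_aucs = fa, mean = m, sd = s,
                 ci_low = unname(ci[1L]), ci_high = unname(ci[2L]),
                 level = level, k = length(fa)),
            class = "fold_auc_summary")
}

#' @export
print.fold_auc_summary <- function(x, ...) {
  cat(sprintf("AUC %.4f +/- %.4f (%d folds), %g%% CI [%.4f, %.4f]\n",
              x$mean, x$sd, x$k, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Final-stage metrics with fold-based AUC interval
#'
#' Precision, recall (TPR), F1 and AUC from the pooled out-of-fold
#' probabilities of the selected stage, plus the mean +/- SD and Student-t
#' confidence interval of the per-fold AUCs.
#'
#' @param oof pooled out-of-fold probabilities.
#' @param y binary labels.
#' @param threshold probability cut-off (default 0.5).
#' @param fold_aucs optional per-fold AUC vector; when supplied the result
#'   carries a [fold_auc_summary()].
#' @param level confidence level for the AUC interval.
#' @return list with `metrics` ([metrics_summary()]) and `fold_auc`
#'   (`fold_auc_summary` or `NULL`).
#' @export
final_metrics <- function(oof, y, threshold = 0.5, fold_aucs = NULL,
                          level = 0.95) {
  list(metrics = metrics_summary(oof, y, threshold),
       fold_auc = if (!is.null(fold_aucs))
         fold_auc_summary(fold_aucs, level))
}

#' Calibration table over fixed-width probability bins
#'
#' Partitions `[0, 1]` into `n_bins` equal-width bins (half-open
#' `[lo, hi)`, last bin closed) and reports, per bin, the patient count, the
#' mean predicted probability and the observed positive fraction. Empty bins
#' carry `empty = TRUE` and `NA` summaries. The count-weighted mean of the
#' observed fractions equals the overall prevalence by construction.
#'
#' @param probs predicted probabilities in \[0, 1\].
#' @param y binary labels.
#' @param n_bins number of bins (default 10).
#' @return data.frame of class `calibration_table`: `bin_lo`, `bin_hi`,
#'   `count`, `mean_pred`, `obs_frac`, `empty`.
#' @export
calibration_bins <- function(probs, y, n_bins = 10L) {
  if (n_bins < 1L) stop("n_bins must be at least 1", call. = FALSE)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  y <- as.integer(y)
  stopifnot(length(probs) == length(y))
  bin <- pmin(floor(probs * n_bins) + 1L, n_bins)
  count <- tabulate(bin, n_bins)
  mean_pred <- obs_frac <- rep(NA_real_, n_bins)
  for (b in which(count > 0L)) {
    sel <- bin == b
    mean_pred[b] <- mean(probs[sel])
    obs_frac[b] <- mean(y[sel])
  }
  out <- data.frame(bin_lo = (seq_len(n_bins) - 1L) / n_bins,
                    bin_hi = seq_len(n_bins) / n_bins,
                    count = count, mean_pred = mean_pred,
                    obs_frac = obs_frac, empty = count == 0L)
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Per-stage probability histograms with positive-case overlay
#'
#' Bins each stage's probabilities at `bin_width`, counting all patients and
#' the positive cases separately — the export behind probability-distribution
#' figures showing how the positive mass migrates across stages.
#'
#' @param stage_oof list of per-stage probability vectors.
#' @param y binary labels.
#' @param bin_width bin width on \[0, 1\] (default 0.05).
#' @return data.frame: `stage`, `bin_lo`, `bin_hi`, `n_all`, `n_pos`.
#' @export
probability_histogram <- function(stage_oof, y, bin_width = 0.05) {
  y <- as.integer(y)
  if (!length(stage_oof)) stop("no stages supplied", call. = FALSE)
  lens <- vapply(stage_oof, length, 0L)
  if (any(lens != length(y)))
    stop("stage probability vectors and y are not conformable",
         call. = FALSE)
  n_bins <- ceiling(1 / bin_width)
  out <- vector("list", length(stage_oof))
  for (i in seq_along(stage_oof)) {
    p <- stage_oof[[i]]
    bin <- pmin(floor(p / bin_width) + 1L, n_bins)
    out[[i]] <- data.frame(stage = i,
                           bin_lo = (seq_len(n_bins) - 1L) * bin_width,
                           bin_hi = pmin(seq_len(n_bins) * bin_width, 1),
                           n_all = tabulate(bin, n_bins),
                           n_pos = tabulate(bin[y == 1L], n_bins))
  }
  do.call(rbind, out)
}
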