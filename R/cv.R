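#' Cross-validated evaluation of a baseline learner
#'
#' Fits one model per fold on the training folds only and scores the held-out
#' fold, so every patient receives an out-of-fold (OOF) probability from a
#' model that never saw their label. Metrics are computed on the pooled OOF
#' probabilities (one confusion matrix over all patients): with 10--126
#' positives among thousands, per-fold rates are too unstable to average.
#'
#' A training split with zero positives cannot fit a two-class model: the
#' fold is skipped with a warning, its patients' probabilities are `NA`, and
#' the skip is recorded in the returned provenance log.
#'
#' @param spec a [learner_spec()] (or registry name).
#' @param X numeric feature matrix.
#' @param y binary 0/1 labels.
#' @param folds a [stratified_folds()] assignment.
#' @param threshold probability cut-off for TPR/TNR (default 0.5).
#' @return a list of class `cv_result`: `metrics` ([metrics_summary()] on
#'   pooled OOF predictions), `oof` (per-patient probabilities, `NA` for
#'   skipped folds), `fold_aucs` (per-fold AUC, `NA` where undefined),
#'   `skipped_folds`, `provenance` (data.frame fold/n_train/n_test/status),
#'   and `fold_fits` (the per-fold fitted learners).
#' @export
cv_evaluate <- function(spec, X, y, folds, threshold = 0.5) {
  if (is.character(spec)) spec <- learner_spec(spec)
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y) || length(folds) != length(y))
    stop("X, y and folds are not conformable", call. = FALSE)
  k <- attr(folds, "k") %||% max(folds)
  oof <- rep(NA_real_, length(y))
  fold_aucs <- rep(NA_real_, k)
  skipped <- integer(0)
  status <- character(k)
  fold_fits <- vector("list", k)
  train_idx_log <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    if (sum(y[train]) == 0L) {
      warning("fold ", f, " skipped: no positives in its training split",
              call. = FALSE)
      skipped <- c(skipped, f)
      status[f] <- "skipped_no_positives"
      next
    }
    fspec <- spec
    fspec$seed <- spec$seed + 101L * f
    fit <- fit_learner(make_learner(fspec),
                       X[train, , drop = FALSE], y[train])
    oof[test] <- predict_proba(fit, X[test, , drop = FALSE])
    fold_aucs[f] <- roc_auc(y[test], oof[test])
    fold_fits[[f]] <- fit
    train_idx_log[[f]] <- train
    status[f] <- "ok"
  }
  structure(list(metrics = metrics_summary(oof, y, threshold),
                 oof = oof,
                 fold_aucs = fold_aucs,
                 skipped_folds = skipped,
                 provenance = data.frame(
                   fold = seq_len(k),
                   n_train = vapply(seq_len(k),
                                    function(f) sum(folds != f), 0L),
                   n_test = vapply(seq_len(k),
                                   function(f) sum(folds == f), 0L),
                   status = status),
                 fold_fits = fold_fits,
                 train_indices = train_idx_log),
            class = "cv_result")
}
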