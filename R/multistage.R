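#' Augment a feature matrix with prior-stage probabilities
#'
#' Appends earlier stages' probability vectors as new feature columns named
#' `stage_prob_<j>`. Under `"cumulative"` mode all history vectors are
#' appended in stage order; under `"last_only"` just the most recent one.
#' Original columns are unchanged and keep their order.
#'
#' @param X feature matrix.
#' @param history list of per-patient probability vectors, one per completed
#'   stage, in stage order. An empty list returns `X` unchanged.
#' @param mode `"cumulative"` (default) or `"last_only"`.
#' @return matrix with `ncol(X) + length(appended)` columns.
#' @export
augment_features <- function(X, history = list(),
                             mode = c("cumulative", "last_only")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (length(history) == 0L) return(X)
  lens <- vapply(history, length, 0L)
  if (any(lens != nrow(X)))
    stop("history vector length (", paste(unique(lens), collapse = ","),
         ") does not match n_patients (", nrow(X), ")", call. = FALSE)
  take <- if (mode == "cumulative") seq_along(history) else length(history)
  add <- do.call(cbind, history[take])
  colnames(add) <- paste0("stage_prob_", take)
  cbind(X, add)
}

#' Run one stage of the multistage chain
#'
#' Cross-validates the base learner on the (possibly augmented) feature
#' matrix — one fit per fold, pooled out-of-fold metrics — and additionally
#' fits one full-data learner kept for inference on new patients.
#'
#' @param spec a [learner_spec()].
#' @param X_aug feature matrix, already augmented for this stage.
#' @param y binary labels.
#' @param folds shared [stratified_folds()] assignment.
#' @param threshold probability cut-off.
#' @return a list of class `stage_result`: `metrics`, `oof`, `fold_aucs`,
#'   `full_fit`, `schema`, `skipped_folds`, `train_indices`.
#' @export
run_stage <- function(spec, X_aug, y, folds, threshold = 0.5) {
  cv <- cv_evaluate(spec, X_aug, y, folds, threshold)
  full <- fit_learner(make_learner(spec), as.matrix(X_aug), y)
  structure(list(metrics = cv$metrics,
                 oof = cv$oof,
                 fold_aucs = cv$fold_aucs,
                 full_fit = full,
                 schema = colnames(as.matrix(X_aug)),
                 skipped_folds = cv$skipped_folds,
                 train_indices = cv$train_indices),
            class = "stage_result")
}

#' Fit a multistage stacked classification model
#'
#' The central procedure: stage 1 cross-validates the base learner on the
#' original features; every later stage appends the previous stages'
#' out-of-fold probabilities as extra feature columns and refits. One fold
#' assignment is fixed up front and reused at every stage, so no fold model
#' ever trains on its held-out patients — directly or through the augmented
#' columns, which are themselves out-of-fold. After `M_max` stages the TPR
#' trajectory is reduced to slope changes and the elbow ([select_stage()])
#' picks the number of stages kept for inference.
#'
#' @param X numeric feature matrix (patients x features).
#' @param y binary 0/1 outcome vector.
#' @param base a [learner_spec()] or registry name; default `easy_ensemble`.
#' @param k folds (default 10).
#' @param M_max stages to explore (>= 3; default 4). The slope-change
#'   statistic needs at least a 3-stage trajectory.
#' @param threshold probability cut-off for TPR/TNR (default 0.5).
#' @param mode augmentation mode, `"cumulative"` (default) or `"last_only"`.
#' @param seed integer; drives fold assignment and all learner fits.
#' @param metric trajectory metric the elbow is computed on; `"tpr"`
#'   (default) or `"auc"`.
#' @param procedure optional outcome name, carried into printed output.
#' @return an object of class `multistage` with components `stages`
#'   (full-data fitted learners, truncated to the selected stage), `trace`
#'   (a `stage_trace` data.frame: stage, tpr, tnr, auc, slope change `s`),
#'   `selected_stage`, `oof` (n x M_max matrix of out-of-fold
#'   probabilities), `fold_aucs` (k x M_max), `folds`, `threshold`, `mode`,
#'   `base`, `schema`, `procedure`.
#' @seealso [predict.multistage()], [slope_changes()], [stage_accounting()]
#' @examples
#' ch <- simulate_cohort(cohort_config(n_patients = 150, n_structured = 12,
#'                                     n_nlp = 4, outcome_spec = c(SCS = 20),
#'                                     seed = 3))
#' m <- multistage(ch$features, ch$labels$SCS, base = "logistic",
#'                 k = 5, M_max = 3, seed = 3)
#' m$selected_stage
#' @export
multistage <- function(X, y, base = "easy_ensemble", k = 10L, M_max = 4L,
                       threshold = 0.5, mode = c("cumulative", "last_only"),
                       seed = 1L, metric = c("tpr", "auc"),
                       procedure = NULL) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  if (M_max < 3L)
    stop("M_max must be at least 3: the slope-change statistic needs a ",
         "trajectory of at least 3 stages", call. = FALSE)
  if (is.character(base)) base <- learner_spec(base, seed = seed)
  X <- as.matrix(X)
  y <- as.integer(y)
  folds <- stratified_folds(y, k, seed)
  history <- list()
  stage_results <- vector("list", M_max)
  for (i in seq_len(M_max)) {
    sspec <- base
    sspec$seed <- base$seed + 1000L * i
    X_aug <- augment_features(X, history, mode)
    stage_results[[i]] <- run_stage(sspec, X_aug, y, folds, threshold)
    history <- c(history, list(stage_results[[i]]$oof))
  }
  p <- vapply(stage_results, function(sr) sr$metrics[[metric]], 0)
  s <- slope_changes(p)
  istar <- select_stage(s)
  trace <- data.frame(
    stage = seq_len(M_max),
    tpr = vapply(stage_results, function(sr) sr$metrics$tpr, 0),
    tnr = vapply(stage_results, function(sr) sr$metrics$tnr, 0),
    auc = vapply(stage_results, function(sr) sr$metrics$auc, 0),
    s = c(NA, s, NA)[seq_len(M_max)])
  attr(trace, "selected_stage") <- istar
  class(trace) <- c("stage_trace", "data.frame")
  structure(list(stages = lapply(stage_results[seq_len(istar)],
                                 function(sr) sr$full_fit),
                 stage_results = stage_results,
                 trace = trace,
                 selected_stage = istar,
                 oof = do.call(cbind, lapply(stage_results, `[[`, "oof")),
                 fold_aucs = do.call(cbind, lapply(stage_results,
                                                   `[[`, "fold_aucs")),
                 folds = folds,
                 threshold = threshold,
                 mode = mode,
                 base = base,
                 schema = colnames(X),
                 procedure = procedure,
                 seed = as.integer(seed)),
            class = "multistage")
}

#' Predict with a fitted multistage model
#'
#' Chains the per-stage full-data models: stage 1 scores the new patients;
#' its probabilities are appended per the augmentation mode; the next
#' stage's model scores the augmented matrix; and so on through the selected
#' stage. Returns the final stage's probabilities.
#'
#' @param object a `multistage` model.
#' @param newdata feature matrix with the training schema.
#' @param ... unused.
#' @return numeric probability vector in \[0, 1\].
#' @export
predict.multistage <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && !is.null(object$schema)) {
    missing_c <- setdiff(object$schema, colnames(X))
    extra_c <- setdiff(colnames(X), object$schema)
    if (length(missing_c) || length(extra_c))
      stop("feature schema mismatch; missing: ",
           paste(missing_c, collapse = ", "),
           "; extra: ", paste(extra_c, collapse = ", "), call. = FALSE)
    X <- X[, object$schema, drop = FALSE]
  } else if (ncol(X) != length(object$schema)) {
    stop("newdata has ", ncol(X), " columns; the model was trained on ",
         length(object$schema), call. = FALSE)
  }
  history <- list()
  probs <- NULL
  for (j in seq_len(object$selected_stage)) {
    X_aug <- augment_features(X, history, object$mode)
    probs <- predict_proba(object$stages[[j]], X_aug)
    history <- c(history, list(probs))
  }
  probs
}

#' @export
print.multistage <- function(x, ...) {
  cat("Multistage", x$base$name, "model")
  if (!is.null(x$procedure)) cat(" for", x$procedure)
  cat("\n")
  cat(sprintf("  %d stage(s) selected of %d explored (%s augmentation)\n",
              x$selected_stage, nrow(x$trace), x$mode))
  sel <- x$trace[x$selected_stage, ]
  cat(sprintf("  selected stage: TPR %.3f | TNR %.3f | AUC %.4f\n",
              sel$tpr, sel$tnr, sel$auc))
  invisible(x)
}

#' @export
summary.multistage <- function(object, ...) {
  structure(list(trace = object$trace,
                 selected_stage = object$selected_stage,
                 base = object$base$name,
                 procedure = object$procedure,
                 fold_auc = fold_auc_summary(
                   object$fold_aucs[, object$selected_stage])),
            class = "summary.multistage")
}

#' @export
print.summary.multistage <- function(x, ...) {
  cat("Multistage", x$base, "model")
  if (!is.null(x$procedure)) cat(" for", x$procedure)
  cat("\n\nStage trajectory (pooled out-of-fold):\n")
  tr <- x$trace
  tr$selected <- ifelse(tr$stage == x$selected_stage, "*", "")
  print.data.frame(format(tr, digits = 4), row.names = FALSE)
  fa <- x$fold_auc
  cat(sprintf(
    "\nSelected stage %d fold AUC: %.4f +/- %.4f, 95%% CI [%.4f, %.4f]\n",
    x$selected_stage, fa$mean, fa$sd, fa$ci_low, fa$ci_high))
  invisible(x)
}

#' Plot the TPR trajectory and its elbow
#'
#' @param x a `multistage` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.multistage <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$stage, tr$tpr, type = "b", pch = 19,
                 xlab = "stage", ylab = "TPR (pooled out-of-fold)",
                 ylim = range(c(tr$tpr, tr$auc)), xaxt = "n", ...)
  graphics::axis(1, at = tr$stage)
  graphics::lines(tr$stage, tr$auc, type = "b", pch = 1, lty = 2)
  graphics::abline(v = x$selected_stage, col = "grey60", lty = 3)
  graphics::legend("bottomright", legend = c("TPR", "AUC", "selected stage"),
                   pch = c(19, 1, NA), lty = c(1, 2, 3),
                   col = c("black", "black", "grey60"), bty = "n")
  invisible(x)
}

#' Export a stage trace as delimited text
#'
#' @param model a `multistage` model (or a `stage_trace`).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_stage_trace <- function(model, path) {
  tr <- if (inherits(model, "multistage")) model$trace else model
  utils::write.table(as.data.frame(tr), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Persist a multistage model to a directory
#'
#' Writes one serialised learner per stage (`stage_<j>.rds`) plus a
#' plain-text `manifest.yaml` (base learner, schema, selected stage,
#' threshold, seed, augmentation mode) and the stage trace as TSV.
#'
#' @param model a `multistage` model.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
export_multistage <- function(model, dir) {
  stopifnot(inherits(model, "multistage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_along(model$stages))
    saveRDS(model$stages[[j]], file.path(dir, sprintf("stage_%d.rds", j)))
  yaml::write_yaml(list(base = model$base$name,
                        selected_stage = model$selected_stage,
                        threshold = model$threshold,
                        mode = model$mode,
                        seed = model$seed,
                        procedure = model$procedure,
                        schema = model$schema),
                   file.path(dir, "manifest.yaml"))
  write_stage_trace(model, file.path(dir, "stage_trace.tsv"))
  invisible(dir)
}
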