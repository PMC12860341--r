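#' Evaluate the full baseline learner grid
#'
#' Cross-validates every registry learner on every procedure outcome with a
#' shared per-procedure fold assignment (so the grid is comparable within a
#' procedure), producing the model-by-procedure table of AUC / TPR / TNR
#' plus each model's min--max range across procedures.
#'
#' @param X feature matrix.
#' @param labels data.frame of binary label columns, one per procedure.
#' @param k folds (default 10).
#' @param seed integer seed shared by fold assignment and all fits.
#' @param threshold probability cut-off (default 0.5).
#' @param models registry names to run (default: all ten).
#' @param hyperparams optional named list of per-model hyperparameter lists.
#' @return a list of class `baseline_suite`: `grid` (long data.frame:
#'   model, procedure, auc, tpr, tnr), `ranges` (per model min/max of each
#'   metric across procedures), and `manifest` (seed, k, threshold, models).
#' @export
run_baseline_suite <- function(X, labels, k = 10L, seed = 1L,
                               threshold = 0.5,
                               models = learner_registry(),
                               hyperparams = list()) {
  X <- as.matrix(X)
  labels <- as.data.frame(labels)
  bad <- setdiff(models, learner_registry())
  if (length(bad))
    stop("unknown learner(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(learner_registry(), collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (proc in names(labels)) {
    y <- as.integer(labels[[proc]])
    folds <- stratified_folds(y, k, seed)   # shared across models
    for (mod in models) {
      spec <- learner_spec(mod, hyperparams[[mod]] %||% list(), seed)
      cv <- cv_evaluate(spec, X, y, folds, threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        model = mod, procedure = proc,
        auc = cv$metrics$auc, tpr = cv$metrics$tpr, tnr = cv$metrics$tnr)
    }
  }
  grid <- do.call(rbind, rows)
  ranges <- do.call(rbind, lapply(split(grid, grid$model), function(g)
    data.frame(model = g$model[1L],
               auc_min = min(g$auc), auc_max = max(g$auc),
               tpr_min = min(g$tpr), tpr_max = max(g$tpr),
               tnr_min = min(g$tnr), tnr_max = max(g$tnr))))
  rownames(ranges) <- NULL
  structure(list(grid = grid, ranges = ranges,
                 manifest = list(seed = seed, k = k, threshold = threshold,
                                 models = models,
                                 hyperparams = hyperparams)),
            class = "baseline_suite")
}

#' @export
print.baseline_suite <- function(x, ...) {
  cat("Baseline suite:", length(unique(x$grid$model)), "models x",
      length(unique(x$grid$procedure)), "procedures\n")
  wide <- stats::reshape(x$grid, idvar = "model", timevar = "procedure",
                         direction = "wide")
  print.data.frame(format(wide, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write the baseline grid and its run manifest
#'
#' @param suite a `baseline_suite`.
#' @param dir output directory; writes `baseline_grid.tsv`,
#'   `baseline_ranges.tsv` and `manifest.yaml`.
#' @return invisibly, `dir`.
#' @export
write_baseline_suite <- function(suite, dir) {
  stopifnot(inherits(suite, "baseline_suite"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(suite$grid, file.path(dir, "baseline_grid.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(suite$ranges, file.path(dir, "baseline_ranges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(suite$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
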