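#' Triage decision for one patient
#'
#' Argmax with a manual-review margin: the highest-probability procedure is
#' scheduled only when its lead over the runner-up strictly exceeds
#' `margin`; otherwise (including exact ties) the case is flagged for manual
#' review by an advanced practice provider. With a single candidate
#' procedure the argmax is always scheduled.
#'
#' @param prob_map named numeric vector: procedure -> final-stage
#'   probability, values in \[0, 1\].
#' @param margin non-negative review margin (default 0.10). A deliberate,
#'   logged clinical trade-off: larger margins push more borderline cases
#'   to human review.
#' @return a list of class `triage_decision`: `outcome` (`"scheduled"` or
#'   `"manual_review"`), `procedure` (scheduled procedure or `NA`),
#'   `top_two` (names of the two highest-probability procedures), `lead`
#'   (top-1 minus top-2 probability), `margin`, `prob_map`.
#' @examples
#' triage_decide(c(SCS = 0.9, ITP = 0.2, PNS = 0.1, BVRF = 0.05,
#'                 MILD = 0.02), margin = 0.1)
#' @export
triage_decide <- function(prob_map, margin = 0.10) {
  if (length(prob_map) == 0L)
    stop("empty probability map", call. = FALSE)
  if (is.null(names(prob_map)) || any(names(prob_map) == ""))
    stop("prob_map must be named by procedure", call. = FALSE)
  if (any(is.na(prob_map)) || any(prob_map < 0 | prob_map > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (margin < 0) stop("margin must be non-negative", call. = FALSE)
  ord <- order(prob_map, decreasing = TRUE)
  top <- names(prob_map)[ord[1L]]
  if (length(prob_map) == 1L) {
    return(structure(list(outcome = "scheduled", procedure = top,
                          top_two = c(top, NA_character_),
                          lead = NA_real_, margin = margin,
                          prob_map = prob_map),
                     class = "triage_decision"))
  }
  second <- names(prob_map)[ord[2L]]
  lead <- unname(prob_map[ord[1L]] - prob_map[ord[2L]])
  scheduled <- lead > margin
  structure(list(outcome = if (scheduled) "scheduled" else "manual_review",
                 procedure = if (scheduled) top else NA_character_,
                 top_two = c(top, second), lead = lead, margin = margin,
                 prob_map = prob_map),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  if (x$outcome == "scheduled")
    cat(sprintf("scheduled(%s), lead %.3f > margin %.3f\n",
                x$procedure, x$lead, x$margin))
  else
    cat(sprintf("manual_review (%s vs %s, lead %.3f <= margin %.3f)\n",
                x$top_two[1L], x$top_two[2L], x$lead, x$margin))
  invisible(x)
}

#' Score and triage a batch of referrals
#'
#' Runs each procedure's multistage model over the feature matrix and
#' applies [triage_decide()] per patient.
#'
#' @param models named list of `multistage` models, one per procedure.
#' @param X feature matrix of new referrals.
#' @param margin review margin (default 0.10).
#' @return data.frame: `patient` (row index), one `prob_<procedure>` column
#'   per model, `outcome`, `procedure`, `lead`.
#' @export
triage_batch <- function(models, X, margin = 0.10) {
  if (!length(models) || is.null(names(models)))
    stop("models must be a named list of multistage models", call. = FALSE)
  probs <- vapply(models, function(m) predict(m, X), numeric(nrow(X)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(X),
                                           dimnames = list(NULL, names(models)))
  out <- data.frame(patient = seq_len(nrow(X)))
  for (proc in colnames(probs)) out[[paste0("prob_", proc)]] <- probs[, proc]
  dec <- apply(probs, 1L, function(p) triage_decide(p, margin))
  out$outcome <- vapply(dec, `[[`, "", "outcome")
  out$procedure <- vapply(dec, `[[`, "", "procedure")
  out$lead <- vapply(dec, function(d) d$lead %||% NA_real_, 0)
  out
}

#' Feature importance of the selected stage
#'
#' Mean impurity-style importance across the final stage's ensemble
#' members: stump ensembles contribute their weighted vote mass per split
#' feature, tree baggers and forests their native importance. Intended for
#' surfacing the top contributing features alongside a recommendation.
#'
#' @param model a `multistage` model.
#' @param top_k number of features to return (default 10).
#' @return data.frame `feature`, `importance`, sorted decreasing.
#' @export
feature_importance <- function(model, top_k = 10L) {
  stopifnot(inherits(model, "multistage"))
  fl <- model$stages[[model$selected_stage]]
  schema <- fl$schema
  imp <- setNames(numeric(length(schema)), schema)
  add_node <- function(node, a) {
    if (is.null(node)) return(invisible())
    f <- node$stump$feature
    if (f > 0L) imp[f] <<- imp[f] + a
    add_node(node$left, a / 2)
    add_node(node$right, a / 2)
  }
  add_ada <- function(ab, w = 1) {
    for (t in seq_along(ab$alphas))
      add_node(ab$trees[[t]], w * ab$alphas[t])
  }
  if (fl$name %in% c("easy_ensemble")) {
    for (m in fl$fit$members) add_ada(m, 1 / length(fl$fit$members))
  } else if (fl$name == "rus_boost") {
    add_ada(fl$fit)
  } else if (fl$name == "balanced_bagging") {
    for (m in fl$fit$members) {
      vi <- m$variable.importance
      if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] +
          vi / length(fl$fit$members)
    }
  } else if (fl$name %in% c("random_forest", "balanced_random_forest")) {
    vi <- randomForest::importance(fl$fit)[, 1L]
    imp[names(vi)] <- vi
  } else if (fl$name %in% c("logistic", "logistic_l1", "logistic_l2")) {
    cf <- if (fl$name == "logistic") stats::coef(fl$fit$model)[-1L]
          else as.numeric(stats::coef(fl$fit$model,
                                      s = fl$fit$lambda))[-1L]
    cf[is.na(cf)] <- 0
    imp[seq_along(cf)] <- abs(cf)
  } else {
    stop("feature importance is not defined for learner '", fl$name, "'",
         call. = FALSE)
  }
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
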