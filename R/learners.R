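#' The closed registry of baseline imbalance-aware learners
#'
#' Ten classifiers spanning three imbalance strategies: undersampling
#' ensembles (`easy_ensemble`, `balanced_bagging`, `rus_boost`,
#' `balanced_random_forest`), balanced class weighting (`random_forest`,
#' `logistic`, `logistic_l1`, `logistic_l2`, `svc`), and one-class novelty
#' modelling of the rare positives (`one_class_svm`).
#'
#' @return character vector of valid learner names.
#' @export
learner_registry <- function() {
  c("easy_ensemble", "balanced_bagging", "rus_boost", "random_forest",
    "balanced_random_forest", "logistic", "logistic_l1", "logistic_l2",
    "one_class_svm", "svc")
}

#' Specify a baseline learner
#'
#' @param name one of [learner_registry()].
#' @param hyperparams named list overriding defaults. Recognised entries:
#'   `n_subsets`, `n_rounds` and `tree_depth` (easy_ensemble), `n_estimators`
#'   (balanced_bagging), `n_rounds` and `tree_depth` (rus_boost), `ntree`
#'   (both random
#'   forests), `lambda` (regularised logistic; default chosen by 5-fold
#'   `cv.glmnet`), `nu` (one_class_svm), `cost` and `gamma` (svc).
#' @param seed integer; propagated to every stochastic component of the fit.
#' @return an object of class `learner_spec`.
#' @export
learner_spec <- function(name, hyperparams = list(), seed = 1L) {
  if (length(name) != 1L || !name %in% learner_registry())
    stop("unknown learner '", name, "'; valid names: ",
         paste(learner_registry(), collapse = ", "), call. = FALSE)
  structure(list(name = name, hyperparams = hyperparams,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

#' Instantiate a learner from its specification
#'
#' Returns a freshly initialised (unfitted) learner bound to its imbalance
#' strategy. Fit it with [fit_learner()] and score with [predict_proba()].
#'
#' @param spec a [learner_spec()], or a registry name (default hyperparams).
#' @return an object of class `base_learner`.
#' @export
make_learner <- function(spec) {
  if (is.character(spec)) spec <- learner_spec(spec)
  stopifnot(inherits(spec, "learner_spec"))
  structure(list(spec = spec), class = "base_learner")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

balanced_case_weights <- function(y) {
  n <- length(y); n1 <- sum(y == 1L); n0 <- n - n1
  ifelse(y == 1L, n / (2 * max(n1, 1L)), n / (2 * max(n0, 1L)))
}

#' Fit a learner
#'
#' @param learner a `base_learner` from [make_learner()].
#' @param X numeric feature matrix (patients x features).
#' @param y binary 0/1 outcome vector.
#' @return an object of class `fitted_learner` carrying the fitted model and
#'   the training column schema.
#' @export
fit_learner <- function(learner, X, y) {
  stopifnot(inherits(learner, "base_learner"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y))
    stop("X and y are not conformable", call. = FALSE)
  spec <- learner$spec
  hp <- spec$hyperparams
  set.seed(spec$seed)
  fit <- switch(spec$name,
    easy_ensemble = fit_easy_ensemble(X, y, hp),
    balanced_bagging = fit_balanced_bagging(X, y, hp),
    rus_boost = fit_rus_boost(X, y, hp),
    random_forest = fit_weighted_rf(X, y, hp),
    balanced_random_forest = fit_balanced_rf(X, y, hp),
    logistic = fit_logistic(X, y, hp, penalty = "none"),
    logistic_l1 = fit_logistic(X, y, hp, penalty = "l1"),
    logistic_l2 = fit_logistic(X, y, hp, penalty = "l2"),
    one_class_svm = fit_one_class_svm(X, y, hp),
    svc = fit_svc(X, y, hp))
  structure(list(name = spec$name, fit = fit, spec = spec,
                 schema = colnames(X)),
            class = "fitted_learner")
}

#' Predicted positive-class probabilities
#'
#' @param object a `fitted_learner`.
#' @param X feature matrix with the training schema (same columns, any
#'   order when named).
#' @return numeric vector in \[0, 1\], one value per row of `X`.
#' @export
predict_proba <- function(object, X) UseMethod("predict_proba")

#' @export
predict_proba.fitted_learner <- function(object, X) {
  X <- as.matrix(X)
  if (!is.null(object$schema) && !is.null(colnames(X))) {
    if (!identical(colnames(X), object$schema)) {
      missing_c <- setdiff(object$schema, colnames(X))
      extra_c <- setdiff(colnames(X), object$schema)
      if (length(missing_c) || length(extra_c))
        stop("feature schema mismatch; missing: ",
             paste(missing_c, collapse = ", "), "; extra: ",
             paste(extra_c, collapse = ", "), call. = FALSE)
      X <- X[, object$schema, drop = FALSE]
    }
  }
  p <- switch(object$name,
    easy_ensemble = predict_easy_ensemble(object$fit, X),
    balanced_bagging = predict_balanced_bagging(object$fit, X),
    rus_boost = adaboost_prob(object$fit, X),
    random_forest = ,
    balanced_random_forest = unname(
      stats::predict(object$fit, X, type = "prob")[, "1"]),
    logistic = predict_logistic_glm(object$fit, X),
    logistic_l1 = ,
    logistic_l2 = as.numeric(
      stats::predict(object$fit$model, newx = X, s = object$fit$lambda,
                     type = "response")),
    one_class_svm = predict_one_class_svm(object$fit, X),
    svc = predict_svc(object$fit, X))
  pmin(pmax(as.numeric(p), 0), 1)
}

# --- undersampling ensembles -------------------------------------------------

fit_easy_ensemble <- function(X, y, hp) {
  n_subsets <- hp$n_subsets %||% 10L
  n_rounds <- hp$n_rounds %||% 50L
  min_cls <- if (sum(y == 1L) <= sum(y == 0L)) 1L else 0L
  idx_min <- which(y == min_cls)
  idx_maj <- which(y != min_cls)
  members <- vector("list", n_subsets)
  for (b in seq_len(n_subsets)) {
    take <- sample(idx_maj, length(idx_min),
                   replace = length(idx_maj) < length(idx_min))
    idx <- c(idx_min, take)
    members[[b]] <- adaboost_fit(X[idx, , drop = FALSE], y[idx], n_rounds,
                                 tree_depth = hp$tree_depth %||% 2L)
  }
  list(members = members)
}

predict_easy_ensemble <- function(fit, X) {
  ps <- vapply(fit$members, function(m) adaboost_prob(m, X),
               numeric(nrow(X)))
  if (is.null(dim(ps))) ps <- matrix(ps, nrow = nrow(X))
  rowMeans(ps)
}

fit_balanced_bagging <- function(X, y, hp) {
  n_estimators <- hp$n_estimators %||% 10L
  min_cls <- if (sum(y == 1L) <= sum(y == 0L)) 1L else 0L
  idx_min <- which(y == min_cls)
  idx_maj <- which(y != min_cls)
  members <- vector("list", n_estimators)
  for (b in seq_len(n_estimators)) {
    idx <- c(sample(idx_min, length(idx_min), replace = TRUE),
             sample(idx_maj, length(idx_min), replace = TRUE))
    d <- data.frame(.y = factor(y[idx], levels = c(0L, 1L)),
                    X[idx, , drop = FALSE], check.names = FALSE)
    # fully grown trees: balanced bags are small (2 x minority count) and
    # the bagging average, not pruning, controls variance
    members[[b]] <- rpart::rpart(.y ~ ., data = d, method = "class",
                                 control = rpart::rpart.control(
                                   minsplit = 2L, minbucket = 1L, cp = 0,
                                   xval = 0))
  }
  list(members = members)
}

predict_balanced_bagging <- function(fit, X) {
  d <- as.data.frame(X, check.names = FALSE)
  ps <- vapply(fit$members,
               function(m) stats::predict(m, d, type = "prob")[, "1"],
               numeric(nrow(X)))
  if (is.null(dim(ps))) ps <- matrix(ps, nrow = nrow(X))
  rowMeans(ps)
}

# AdaBoost where each round's weak learner is trained on a balanced random
# undersample of the majority class (sampled by current boosting weights);
# errors and weight updates use the full training set.
fit_rus_boost <- function(X, y, hp) {
  n_rounds <- hp$n_rounds %||% 50L
  n <- nrow(X)
  if (length(unique(y)) < 2L)
    return(structure(list(trees = list(), alphas = numeric(0),
                          constant = mean(y)), class = "adaboost"))
  min_cls <- if (sum(y == 1L) <= sum(y == 0L)) 1L else 0L
  idx_min <- which(y == min_cls)
  idx_maj <- which(y != min_cls)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (t in seq_len(n_rounds)) {
    k <- min(length(idx_min), length(idx_maj))
    take <- sample(idx_maj, k, prob = w[idx_maj])
    idx <- c(idx_min, take)
    st <- wtree_fit(X[idx, , drop = FALSE], y[idx], w[idx],
                    hp$tree_depth %||% 2L)
    h <- wtree_predict(st, X)
    err <- sum(w[h != y]) / sum(w)
    if (err >= 0.5) break
    alpha <- if (err <= 0) 10 else 0.5 * log((1 - err) / err)
    trees <- c(trees, list(st)); alphas <- c(alphas, alpha)
    if (err <= 0) break
    w <- w * exp(alpha * (h != y))
    w <- w / sum(w)
  }
  if (length(alphas) == 0L)
    return(structure(list(trees = list(), alphas = numeric(0),
                          constant = mean(y)), class = "adaboost"))
  structure(list(trees = trees, alphas = alphas, constant = NULL),
            class = "adaboost")
}

# --- forests -----------------------------------------------------------------

fit_weighted_rf <- function(X, y, hp) {
  fy <- factor(y, levels = c(0L, 1L))
  cw <- c("0" = 1 / max(sum(y == 0L), 1L), "1" = 1 / max(sum(y == 1L), 1L))
  randomForest::randomForest(x = X, y = fy, ntree = hp$ntree %||% 100L,
                             classwt = cw / sum(cw))
}

fit_balanced_rf <- function(X, y, hp) {
  fy <- factor(y, levels = c(0L, 1L))
  n_min <- min(table(fy))
  randomForest::randomForest(x = X, y = fy, ntree = hp$ntree %||% 100L,
                             strata = fy, sampsize = c(n_min, n_min),
                             replace = TRUE)
}

# --- logistic family ---------------------------------------------------------

fit_logistic <- function(X, y, hp, penalty) {
  w <- balanced_case_weights(y)
  if (penalty == "none") {
    d <- data.frame(.y = y, X, check.names = FALSE)
    # quasibinomial: identical fit to binomial, silent under fractional weights
    m <- suppressWarnings(stats::glm(.y ~ ., data = d,
                                     family = stats::quasibinomial(),
                                     weights = w))
    return(list(model = m, schema = colnames(X)))
  }
  alpha <- if (penalty == "l1") 1 else 0
  lambda <- hp$lambda
  if (is.null(lambda)) {
    cvm <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                             weights = w, nfolds = 5L)
    lambda <- cvm$lambda.min
    model <- cvm$glmnet.fit
  } else {
    model <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                            weights = w)
  }
  list(model = model, lambda = lambda)
}

predict_logistic_glm <- function(fit, X) {
  d <- as.data.frame(X, check.names = FALSE)
  suppressWarnings(stats::predict(fit$model, newdata = d, type = "response"))
}

# --- SVMs --------------------------------------------------------------------

fit_svc <- function(X, y, hp) {
  fy <- factor(y, levels = c(0L, 1L))
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  cw <- table(fy); cw <- sum(cw) / (2 * pmax(cw, 1))
  m <- suppressWarnings(
    e1071::svm(x = X[, keep, drop = FALSE], y = fy, kernel = "radial",
               cost = hp$cost %||% 1, gamma = hp$gamma %||% (1 / sum(keep)),
               class.weights = cw, probability = TRUE))
  list(model = m, keep = keep)
}

predict_svc <- function(fit, X) {
  pr <- stats::predict(fit$model, X[, fit$keep, drop = FALSE],
                       probability = TRUE)
  attr(pr, "probabilities")[, "1"]
}

# One-class SVM fit on the positive class only; decision scores are min-max
# rescaled to [0,1] per prediction batch so they behave like probabilities.
fit_one_class_svm <- function(X, y, hp) {
  pos <- X[y == 1L, , drop = FALSE]
  if (nrow(pos) < 2L)
    stop("one_class_svm needs at least two positive cases", call. = FALSE)
  keep <- apply(pos, 2L, function(v) stats::sd(v) > 0)
  if (!any(keep)) keep[] <- TRUE
  m <- suppressWarnings(
    e1071::svm(x = pos[, keep, drop = FALSE], type = "one-classification",
               nu = hp$nu %||% 0.5, kernel = "radial",
               gamma = hp$gamma %||% (1 / sum(keep)), scale = FALSE))
  list(model = m, keep = keep)
}

predict_one_class_svm <- function(fit, X) {
  dv <- attr(stats::predict(fit$model, X[, fit$keep, drop = FALSE],
                            decision.values = TRUE), "decision.values")
  dv <- as.numeric(dv)
  rng <- range(dv)
  if (diff(rng) == 0) return(rep(0.5, length(dv)))
  (dv - rng[1L]) / diff(rng)
}
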