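# Cheap easy-ensemble configuration used across multistage tests.
ee_small <- function(seed) {
  learner_spec("easy_ensemble",
               hyperparams = list(n_subsets = 4L, n_rounds = 10L),
               seed = seed)
}

test_that("augmentation appends stage probability columns in order", {
  ch <- small_cohort(seed = 2, n = 60, pos = 10)
  X <- ch$features
  y1 <- runif(60); y2 <- runif(60)
  A1 <- augment_features(X, list(y1))
  expect_equal(ncol(A1), ncol(X) + 1)
  expect_identical(colnames(A1)[ncol(A1)], "stage_prob_1")
  expect_identical(A1[, seq_len(ncol(X))], X)
  A2 <- augment_features(X, list(y1, y2), mode = "cumulative")
  expect_equal(ncol(A2), ncol(X) + 2)
  expect_identical(colnames(A2)[ncol(X) + 1:2],
                   c("stage_prob_1", "stage_prob_2"))
  A3 <- augment_features(X, list(y1, y2), mode = "last_only")
  expect_equal(ncol(A3), ncol(X) + 1)
  expect_identical(colnames(A3)[ncol(A3)], "stage_prob_2")
  expect_identical(augment_features(X, list()), X)
  expect_error(augment_features(X, list(runif(10))), "does not match")
})

test_that("column count at stage j is n + (j - 1) in cumulative mode", {
  X <- matrix(runif(50), 10, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  history <- list()
  for (j in 1:4) {
    expect_equal(ncol(augment_features(X, history)), 5 + (j - 1))
    history <- c(history, list(runif(10)))
  }
})

test_that("an oracle meta-feature drives TPR to one", {
  ch <- small_cohort(seed = 12, n = 150, pos = 20, noise_scale = 3)
  y <- ch$labels$SCS
  folds <- stratified_folds(y, 5, 12)
  X_aug <- augment_features(ch$features, list(as.numeric(y)))
  sr <- run_stage(ee_small(12), X_aug, y, folds)
  expect_equal(sr$metrics$tpr, 1)
})

test_that("M_max below three is rejected", {
  ch <- small_cohort(seed = 1, n = 60, pos = 10)
  expect_error(multistage(ch$features, ch$labels$SCS, base = "logistic",
                          k = 3, M_max = 2, seed = 1),
               "at least 3")
})

test_that("multistage fit selects the elbow of its own trajectory", {
  ch <- small_cohort(seed = 21, n = 200, pos = 30)
  m <- multistage(ch$features, ch$labels$SCS, base = ee_small(21),
                  k = 5, M_max = 4, seed = 21)
  expect_s3_class(m, "multistage")
  s <- slope_changes(m$trace$tpr)
  expect_identical(m$selected_stage, select_stage(s))
  expect_true(m$selected_stage %in% 2:3)
  expect_length(m$stages, m$selected_stage)
  expect_equal(dim(m$oof), c(200L, 4L))
  expect_true(all(m$oof >= 0 & m$oof <= 1))
})

test_that("identical seeds give bit-identical stage traces", {
  ch <- small_cohort(seed = 33, n = 120, pos = 18)
  m1 <- multistage(ch$features, ch$labels$SCS, base = ee_small(33),
                   k = 4, M_max = 3, seed = 33)
  m2 <- multistage(ch$features, ch$labels$SCS, base = ee_small(33),
                   k = 4, M_max = 3, seed = 33)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$oof, m2$oof)
})

test_that("stage results are immutable as later stages are added", {
  ch <- small_cohort(seed = 41, n = 120, pos = 18)
  y <- ch$labels$SCS
  m3 <- multistage(ch$features, y, base = ee_small(41), k = 4, M_max = 3,
                   seed = 41)
  m4 <- multistage(ch$features, y, base = ee_small(41), k = 4, M_max = 4,
                   seed = 41)
  expect_equal(m3$trace$tpr, m4$trace$tpr[1:3])
  expect_equal(m3$trace$auc, m4$trace$auc[1:3])
})

test_that("prediction chains the stage models and respects the schema", {
  ch <- small_cohort(seed = 51, n = 150, pos = 25)
  y <- ch$labels$SCS
  m <- multistage(ch$features, y, base = ee_small(51), k = 5, M_max = 3,
                  seed = 51)
  p <- predict(m, ch$features)
  expect_length(p, 150)
  expect_true(all(p >= 0 & p <= 1))
  # schema errors name the offending columns
  X_bad <- ch$features[, -3]
  expect_error(predict(m, X_bad), colnames(ch$features)[3])
  X_extra <- cbind(ch$features, junk = 1)
  expect_error(predict(m, X_extra), "junk")
})

test_that("a single-stage chain predicts like its base learner", {
  ch <- small_cohort(seed = 61, n = 100, pos = 15)
  y <- ch$labels$SCS
  m <- multistage(ch$features, y, base = ee_small(61), k = 4, M_max = 3,
                  seed = 61)
  # force a one-stage chain and compare with the stage-1 full fit
  m1 <- m
  m1$selected_stage <- 1L
  m1$stages <- m$stages[1]
  expect_identical(predict(m1, ch$features),
                   predict_proba(m$stage_results[[1]]$full_fit,
                                 ch$features))
})

test_that("a hand-traced two-stage logistic chain reproduces predict", {
  # 3 training patients, one feature; trace the chain by hand via the
  # same fitted stage models
  set.seed(71)
  X <- matrix(c(0, 1, 2, 0.5, 1.5, 2.5), 6, 1,
              dimnames = list(NULL, "x"))
  y <- c(0L, 0L, 1L, 0L, 1L, 1L)
  suppressWarnings({
    m <- multistage(X, y, base = learner_spec("logistic", seed = 71),
                    k = 2, M_max = 3, seed = 71)
  })
  m$selected_stage <- 2L
  m$stages <- lapply(m$stage_results[1:2], `[[`, "full_fit")
  p_hand1 <- predict_proba(m$stages[[1]], X)
  X2 <- cbind(X, stage_prob_1 = p_hand1)
  p_hand2 <- predict_proba(m$stages[[2]], X2)
  expect_equal(predict(m, X), p_hand2, tolerance = 1e-12)
})

test_that("stage trace serialises to delimited text", {
  ch <- small_cohort(seed = 81, n = 100, pos = 15)
  m <- multistage(ch$features, ch$labels$SCS, base = ee_small(81), k = 4,
                  M_max = 3, seed = 81)
  path <- tempfile(fileext = ".tsv")
  write_stage_trace(m, path)
  back <- read.delim(path)
  expect_equal(back$tpr, m$trace$tpr)
  expect_equal(nrow(back), 3)
})

test_that("feature importance surfaces the selected stage's top features", {
  ch <- small_cohort(seed = 91, n = 150, pos = 25, noise_scale = 1.5)
  m <- multistage(ch$features, ch$labels$SCS, base = ee_small(91), k = 4,
                  M_max = 3, seed = 91)
  imp <- feature_importance(m, top_k = 5)
  expect_equal(nrow(imp), 5)
  expect_true(all(imp$feature %in% c(colnames(ch$features),
                                     paste0("stage_prob_", 1:2))))
  expect_true(all(diff(imp$importance) <= 0))
})
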