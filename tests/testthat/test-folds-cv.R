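test_that("stratified folds balance positives to within one", {
  y <- rep(c(1L, 0L), c(10, 90))
  f <- stratified_folds(y, 10, 1)
  expect_equal(as.integer(table(f[y == 1])), rep(1L, 10))
  # 16 positives over 10 folds: six folds of 2, four of 1
  y2 <- rep(c(1L, 0L), c(16, 184))
  f2 <- stratified_folds(y2, 10, 2)
  cnt <- sort(unname(table(factor(f2[y2 == 1], levels = 1:10))))
  expect_equal(as.integer(cnt), c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L))
  # every patient in exactly one fold; total sizes within one
  expect_length(f2, 200)
  expect_lte(diff(range(table(f2))), 1)
})

test_that("fold assignment edge cases error or warn as contracted", {
  y <- rep(c(1L, 0L), c(5, 45))
  expect_error(stratified_folds(y, 1, 1), "at least 2")
  expect_error(stratified_folds(y, 51, 1), "exceeds")
  expect_warning(stratified_folds(y, 10, 1), "degenerate")
  expect_identical(stratified_folds(y, 5, 3), stratified_folds(y, 5, 3))
})

test_that("confusion metrics match the brute-force oracle", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0) next
    pr <- runif(n)
    th <- runif(1, 0.2, 0.8)
    m <- metrics_summary(pr, y, th)
    cm <- confusion_oracle(pr, y, th)
    expect_equal(m$tpr, cm["tp"] / (cm["tp"] + cm["fn"]),
                 ignore_attr = TRUE)
    expect_equal(m$tnr, cm["tn"] / (cm["tn"] + cm["fp"]),
                 ignore_attr = TRUE)
  }
})

test_that("a probability equal to the threshold is called negative", {
  y <- c(1L, 1L, 0L)
  m <- metrics_summary(c(0.5, 0.6, 0.5), y, 0.5)
  expect_equal(unname(m$confusion["tp"]), 1L)
  expect_equal(unname(m$confusion["fn"]), 1L)
  expect_equal(unname(m$confusion["tn"]), 1L)
})

test_that("AUC agrees with the Mann-Whitney pairwise oracle", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(40:200, 1)
    y <- rbinom(n, 1, 0.25)
    if (sum(y) == 0 || sum(y) == n) next
    pr <- round(runif(n), 2)  # induce ties
    m <- metrics_summary(pr, y)
    expect_equal(m$auc, auc_pairwise_oracle(y, pr), tolerance = 1e-10)
  }
})

test_that("recall and TPR are one and the same field", {
  set.seed(99)
  m <- metrics_summary(runif(50), rbinom(50, 1, 0.3))
  expect_identical(m$recall, m$tpr)
})

test_that("constant probabilities give chance AUC and the tie rule TPR", {
  y <- rep(c(1L, 0L), c(10, 30))
  pr <- rep(0.5, 40)
  m <- metrics_summary(pr, y, 0.5)
  expect_equal(m$auc, 0.5)
  expect_equal(m$tpr, 0)   # equal-to-threshold is negative
  expect_equal(m$tnr, 1)
})

test_that("cv_evaluate pools out-of-fold predictions per patient", {
  ch <- small_cohort(seed = 6, n = 150, pos = 25)
  y <- ch$labels$SCS
  folds <- stratified_folds(y, 5, 6)
  cv <- cv_evaluate(learner_spec("logistic", seed = 6), ch$features, y,
                    folds)
  expect_false(anyNA(cv$oof))
  expect_true(all(cv$oof >= 0 & cv$oof <= 1))
  # every fold model trained without its own fold
  for (f in 1:5)
    expect_length(intersect(cv$train_indices[[f]], which(folds == f)), 0)
})

test_that("training splits without positives are skipped with a warning", {
  # 2 positives in one fold of 3: leaving that fold out empties the
  # training positives for it only when both positives share a fold
  y <- c(1L, 1L, rep(0L, 28))
  folds <- structure(rep(1:3, length.out = 30), k = 3L,
                     class = "fold_assignment")
  folds[1:2] <- 1L   # both positives in fold 1
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(
    cv <- cv_evaluate(learner_spec("logistic", seed = 1), X, y, folds,
                      threshold = 0.5),
    "no positives")
  expect_equal(cv$skipped_folds, 1L)
  expect_true(all(is.na(cv$oof[folds == 1])))
  expect_identical(cv$provenance$status[1], "skipped_no_positives")
})

test_that("hand-set probabilities reproduce a hand confusion matrix", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 1, 0)
  pr <- c(0.9, 0.4, 0.6, 0.2, 0.7, 0.1, 0.5, 0.3, 0.55, 0.45)
  m <- metrics_summary(pr, y, 0.5)
  # by hand: TP {0.9,0.6,0.55}, FN {0.4}; TN {0.2,0.1,0.5,0.3,0.45}, FP {0.7}
  expect_equal(unname(m$confusion), c(3L, 1L, 5L, 1L))
  expect_equal(m$tpr, 3 / 4)
  expect_equal(m$tnr, 5 / 6)
})
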