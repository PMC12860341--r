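# Baseline suite runs use a compact cohort and a trimmed model list so the
# grid stays cheap; the full registry is exercised one model at a time in
# test-base-learners.R.

test_that("the suite grid is internally consistent with its ranges", {
  ch <- simulate_cohort(cohort_config(
    n_patients = 160, n_structured = 12, n_nlp = 4,
    outcome_spec = c(PNS = 12L, SCS = 24L), signal_sparsity = 0.25,
    noise_scale = 2, seed = 301))
  suite <- suppressWarnings(run_baseline_suite(
    ch$features, ch$labels, k = 4, seed = 301,
    models = c("easy_ensemble", "balanced_bagging", "logistic"),
    hyperparams = list(easy_ensemble = list(n_subsets = 3L,
                                            n_rounds = 8L))))
  expect_equal(nrow(suite$grid), 6)
  expect_true(all(suite$grid$auc >= 0 & suite$grid$auc <= 1))
  for (mod in unique(suite$grid$model)) {
    g <- suite$grid[suite$grid$model == mod, ]
    r <- suite$ranges[suite$ranges$model == mod, ]
    expect_equal(r$auc_min, min(g$auc))
    expect_equal(r$auc_max, max(g$auc))
    expect_equal(r$tpr_min, min(g$tpr))
    expect_equal(r$tnr_max, max(g$tnr))
  }
  expect_equal(suite$manifest$seed, 301)
})

test_that("unknown models are rejected with the registry listed", {
  ch <- small_cohort(seed = 302, n = 60, pos = 10)
  expect_error(run_baseline_suite(ch$features, ch$labels,
                                  models = c("logistic", "adaboost")),
               "easy_ensemble")
})

test_that("null cohorts score near chance for every model run", {
  aucs <- sapply(c(311, 312, 313), function(sd) {
    ch <- simulate_cohort(cohort_config(
      n_patients = 200, n_structured = 12, n_nlp = 4,
      outcome_spec = c(SCS = 30L), signal_sparsity = 0,
      noise_scale = 1, seed = sd))
    suite <- suppressWarnings(run_baseline_suite(
      ch$features, ch$labels, k = 4, seed = sd,
      models = c("logistic", "balanced_bagging")))
    suite$grid$auc
  })
  expect_true(all(aucs > 0.3 & aucs < 0.7))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("the suite is deterministic given its seed", {
  ch <- small_cohort(seed = 321, n = 100, pos = 15)
  s1 <- run_baseline_suite(ch$features, ch$labels, k = 4, seed = 9,
                           models = "balanced_bagging")
  s2 <- run_baseline_suite(ch$features, ch$labels, k = 4, seed = 9,
                           models = "balanced_bagging")
  expect_identical(s1$grid, s2$grid)
})

test_that("suite exports round-trip as delimited text", {
  ch <- small_cohort(seed = 331, n = 80, pos = 12)
  suite <- run_baseline_suite(ch$features, ch$labels, k = 4, seed = 331,
                              models = "logistic")
  dir <- tempfile("suite")
  write_baseline_suite(suite, dir)
  back <- read.delim(file.path(dir, "baseline_grid.tsv"))
  expect_equal(back$auc, suite$grid$auc)
  mf <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(mf$k, 4)
})

test_that("easy ensemble outranks the one-class SVM on planted signal", {
  wins <- sapply(c(601, 602, 603), function(sd) {
    ch <- small_cohort(seed = sd, n = 200, pos = 25, noise_scale = 1.5)
    folds <- stratified_folds(ch$labels$SCS, 4, sd)
    ee <- cv_evaluate(learner_spec("easy_ensemble",
                                   list(n_subsets = 4L, n_rounds = 10L),
                                   seed = sd),
                      ch$features, ch$labels$SCS, folds)
    oc <- cv_evaluate(learner_spec("one_class_svm", seed = sd),
                      ch$features, ch$labels$SCS, folds)
    ee$metrics$auc >= oc$metrics$auc
  })
  expect_gte(sum(wins), 2)
})
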