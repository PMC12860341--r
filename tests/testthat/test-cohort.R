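test_that("default configuration has the study cohort shape", {
  cfg <- cohort_config()
  expect_equal(cfg$n_patients, 3552L)
  expect_equal(cfg$n_structured + cfg$n_nlp, 231L)
  expect_equal(unname(cfg$outcome_spec[c("PNS", "SCS", "ITP", "BVRF",
                                         "MILD")]),
               c(46L, 126L, 36L, 16L, 10L))
})

test_that("generated cohorts honour exact positive counts and shape", {
  ch <- small_cohort(seed = 1, n = 300, pos = 25)
  expect_equal(dim(ch$features), c(300L, 20L))
  expect_equal(sum(ch$labels$SCS), 25)
  expect_false(anyNA(ch$features))
  # NLP columns strictly binary
  nlp <- ch$features[, ch$feature_kind == "nlp_flag", drop = FALSE]
  expect_true(all(nlp %in% c(0, 1)))
  # multiple outcomes: counts exact for each
  ch2 <- simulate_cohort(cohort_config(
    n_patients = 200, n_structured = 10, n_nlp = 5,
    outcome_spec = c(A = 7L, B = 30L, C = 0L), seed = 5))
  expect_equal(unname(colSums(ch2$labels)), c(7, 30, 0))
})

test_that("generation is bit-identical under a fixed seed", {
  a <- small_cohort(seed = 9)
  b <- small_cohort(seed = 9)
  expect_identical(a$features, b$features)
  expect_identical(a$labels, b$labels)
  c2 <- small_cohort(seed = 10)
  expect_false(identical(a$features, c2$features))
})

test_that("boundary label counts work", {
  ch <- simulate_cohort(cohort_config(n_patients = 50, n_structured = 6,
                                      n_nlp = 2,
                                      outcome_spec = c(SCS = 50L),
                                      seed = 2))
  expect_true(all(ch$labels$SCS == 1))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), "positive count")
  expect_error(cohort_config(n_structured = 0, n_nlp = 0), "feature")
  expect_error(cohort_config(n_patients = 10,
                             outcome_spec = c(SCS = 11L)),
               "exceeds n_patients")
  expect_error(cohort_config(outcome_spec = c(SCS = -1L)), "non-negative")
})

test_that("planted linear signal is learnable; null cohorts are not", {
  # noiseless, interaction-free cohort: logistic CV AUC far above chance
  ch <- simulate_cohort(cohort_config(
    n_patients = 250, n_structured = 16, n_nlp = 4,
    outcome_spec = c(SCS = 40L), signal_sparsity = 0.25,
    interaction_pairs = 0L, noise_scale = 0, seed = 13))
  folds <- stratified_folds(ch$labels$SCS, 5, 13)
  cv <- cv_evaluate(learner_spec("logistic", seed = 13), ch$features,
                    ch$labels$SCS, folds)
  expect_gt(cv$metrics$auc, 0.95)

  # zero-sparsity cohorts: AUC hovers around chance (3 seeds)
  aucs <- sapply(c(101, 202, 303), function(sd) {
    chn <- simulate_cohort(cohort_config(
      n_patients = 250, n_structured = 16, n_nlp = 4,
      outcome_spec = c(SCS = 40L), signal_sparsity = 0,
      interaction_pairs = 0L, noise_scale = 1, seed = sd))
    f <- stratified_folds(chn$labels$SCS, 5, sd)
    cv_evaluate(learner_spec("logistic", seed = sd), chn$features,
                chn$labels$SCS, f)$metrics$auc
  })
  expect_true(all(aucs > 0.35 & aucs < 0.65))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("cohort round-trips through delimited text", {
  ch <- small_cohort(seed = 31, n = 60, pos = 8)
  dir <- tempfile("cohort")
  write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "metadata.yaml")))
  back <- read_cohort(dir)
  expect_equal(unname(back$features), unname(ch$features))
  expect_equal(back$labels$SCS, ch$labels$SCS)
  expect_equal(back$config$seed, 31)
})
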