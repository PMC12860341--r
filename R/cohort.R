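#' Configuration for a synthetic referral cohort
#'
#' Describes the statistical shape of a referral cohort: number of patients,
#' the split between structured features (medication counts, appointment
#' histories, comorbidity flags) and binary NLP concept flags extracted from
#' clinical notes, exact positive counts per procedure outcome, and the
#' planted-signal structure of the latent scores that drive the labels.
#'
#' The defaults reproduce the shape of a two-year internal pain-medicine
#' referral cohort: 3,552 patients, 192 structured plus 39 NLP features, and
#' per-procedure positive counts PNS 46, SCS 126, ITP 36, BVRF 16, MILD 10 --
#' prevalences between 0.3% and 3.5%, i.e. heavy class imbalance.
#'
#' @param n_patients number of rows (patients).
#' @param n_structured number of structured feature columns.
#' @param n_nlp number of binary NLP concept-flag columns.
#' @param outcome_spec named integer vector: exact positive count per
#'   procedure. Names become the procedure labels.
#' @param signal_sparsity fraction of feature columns with a nonzero linear
#'   effect on each outcome's latent score.
#' @param interaction_pairs number of pairwise feature interactions added to
#'   each outcome's latent score. Interactions give tree ensembles (and
#'   stage augmentation) headroom over a single linear fit.
#' @param noise_scale standard deviation of the Gaussian noise added to each
#'   latent score.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_patients = 3552L,
                          n_structured = 192L,
                          n_nlp = 39L,
                          outcome_spec = c(PNS = 46L, SCS = 126L, ITP = 36L,
                                           BVRF = 16L, MILD = 10L),
                          signal_sparsity = 0.05,
                          interaction_pairs = 5L,
                          noise_scale = 2.5,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_structured = as.integer(n_structured),
              n_nlp = as.integer(n_nlp),
              outcome_spec = outcome_spec,
              signal_sparsity = signal_sparsity,
              interaction_pairs = as.integer(interaction_pairs),
              noise_scale = noise_scale,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1L)
    stop("invalid config: n_patients must be a positive count", call. = FALSE)
  if (cfg$n_structured + cfg$n_nlp < 1L)
    stop("invalid config: at least one feature column is required",
         call. = FALSE)
  if (cfg$n_structured < 0L || cfg$n_nlp < 0L)
    stop("invalid config: feature counts must be non-negative", call. = FALSE)
  if (is.null(names(cfg$outcome_spec)) || any(names(cfg$outcome_spec) == ""))
    stop("invalid config: outcome_spec must be a named vector", call. = FALSE)
  if (any(cfg$outcome_spec < 0L))
    stop("invalid config: positive counts must be non-negative", call. = FALSE)
  if (any(cfg$outcome_spec > cfg$n_patients))
    stop("invalid config: positive count exceeds n_patients for ",
         paste(names(cfg$outcome_spec)[cfg$outcome_spec > cfg$n_patients],
               collapse = ", "), call. = FALSE)
  if (cfg$signal_sparsity < 0 || cfg$signal_sparsity > 1)
    stop("invalid config: signal_sparsity must lie in [0, 1]", call. = FALSE)
  if (cfg$noise_scale < 0)
    stop("invalid config: noise_scale must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' Simulate a synthetic referral cohort
#'
#' Draws a feature matrix and per-procedure binary outcome labels with the
#' configured shape. Structured columns are a half-and-half mix of binary
#' flags (Bernoulli, occurrence rates 0.05--0.5) and non-negative counts
#' (Poisson, rates 0.2--3), mimicking comorbidity indicators and visit or
#' medication counts; NLP columns are strictly binary concept flags
#' (rates 0.02--0.3).
#'
#' Each outcome's latent score is a sparse linear combination of standardised
#' features (scaled to SD 1.5), plus `interaction_pairs` pairwise products of
#' signal features (jointly scaled to SD 1), plus Gaussian noise of SD
#' `noise_scale`. Labels are assigned by ranking the latent score and marking
#' exactly the configured number of top-ranked patients positive, so positive
#' counts are exact and downstream tests deterministic. Outcomes are drawn
#' independently per procedure; a patient may be positive for several.
#'
#' @param config a [cohort_config()].
#' @return an object of class `referral_cohort`: a list with `features`
#'   (numeric matrix, patients x features), `labels` (data.frame of 0/1
#'   columns, one per procedure), `feature_kind` (character,
#'   `"structured"` or `"nlp_flag"` per column), and `config`.
#' @examples
#' ch <- simulate_cohort(cohort_config(n_patients = 200, n_structured = 20,
#'                                     n_nlp = 5, outcome_spec = c(SCS = 12),
#'                                     seed = 7))
#' dim(ch$features)
#' colSums(ch$labels)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_patients
  p_str <- config$n_structured
  p_nlp <- config$n_nlp
  p_tot <- p_str + p_nlp

  n_bin <- p_str %/% 2L
  n_cnt <- p_str - n_bin
  cols <- vector("list", p_tot)
  if (n_bin > 0L) {
    rates <- stats::runif(n_bin, 0.05, 0.5)
    for (j in seq_len(n_bin))
      cols[[j]] <- stats::rbinom(n, 1L, rates[j])
  }
  if (n_cnt > 0L) {
    lam <- stats::runif(n_cnt, 0.2, 3)
    for (j in seq_len(n_cnt))
      cols[[n_bin + j]] <- stats::rpois(n, lam[j])
  }
  if (p_nlp > 0L) {
    rates <- stats::runif(p_nlp, 0.02, 0.3)
    for (j in seq_len(p_nlp))
      cols[[p_str + j]] <- stats::rbinom(n, 1L, rates[j])
  }
  X <- do.call(cbind, cols)
  storage.mode(X) <- "double"
  feature_names <- c(if (p_str > 0L) sprintf("struct_%03d", seq_len(p_str)),
                     if (p_nlp > 0L) sprintf("nlp_%02d", seq_len(p_nlp)))
  colnames(X) <- feature_names
  feature_kind <- rep(c("structured", "nlp_flag"), c(p_str, p_nlp))

  # standardised copy used only to build latent scores
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0 | is.na(attr(Z, "scaled:scale"))] <- 0
  Z[is.na(Z)] <- 0

  labels <- matrix(0L, n, length(config$outcome_spec),
                   dimnames = list(NULL, names(config$outcome_spec)))
  for (oc in names(config$outcome_spec)) {
    k_pos <- config$outcome_spec[[oc]]
    n_sig <- round(config$signal_sparsity * p_tot)
    score <- numeric(n)
    if (n_sig >= 1L) {
      sig <- sample.int(p_tot, n_sig)
      beta <- stats::rnorm(n_sig)
      lin <- drop(Z[, sig, drop = FALSE] %*% beta)
      if (stats::sd(lin) > 0) lin <- lin * (1.5 / stats::sd(lin))
      score <- score + lin
      if (config$interaction_pairs > 0L && n_sig >= 2L) {
        inter <- numeric(n)
        for (q in seq_len(config$interaction_pairs)) {
          pr <- sample(sig, 2L)
          inter <- inter + sample(c(-1, 1), 1L) * Z[, pr[1L]] * Z[, pr[2L]]
        }
        if (stats::sd(inter) > 0) inter <- inter / stats::sd(inter)
        score <- score + inter
      }
    }
    score <- score + stats::rnorm(n, sd = config$noise_scale)
    if (k_pos > 0L)
      labels[order(score, decreasing = TRUE)[seq_len(k_pos)], oc] <- 1L
  }

  structure(list(features = X,
                 labels = as.data.frame(labels),
                 feature_kind = feature_kind,
                 config = config),
            class = "referral_cohort")
}

#' @export
print.referral_cohort <- function(x, ...) {
  cat("Synthetic referral cohort\n")
  cat(sprintf("  %d patients, %d features (%d structured, %d NLP flags)\n",
              nrow(x$features), ncol(x$features),
              sum(x$feature_kind == "structured"),
              sum(x$feature_kind == "nlp_flag")))
  pos <- colSums(x$labels)
  cat("  positives:",
      paste(sprintf("%s=%d", names(pos), pos), collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort to delimited text
#'
#' Writes `cohort.csv` (features plus one `label_<PROCEDURE>` column per
#' procedure), `config.yaml` (the generating configuration, seed included)
#' and `metadata.yaml` (dimensions, positive counts, seed) into `dir`.
#'
#' @param cohort a `referral_cohort`.
#' @param dir output directory, created if missing.
#' @return invisibly, the path to the cohort CSV.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "referral_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- as.data.frame(cohort$features)
  for (oc in names(cohort$labels))
    tab[[paste0("label_", oc)]] <- cohort$labels[[oc]]
  path <- file.path(dir, "cohort.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  cfg$outcome_spec <- as.list(cfg$outcome_spec)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  yaml::write_yaml(list(n_patients = nrow(cohort$features),
                        n_features = ncol(cohort$features),
                        positives = as.list(colSums(cohort$labels)),
                        seed = cohort$config$seed),
                   file.path(dir, "metadata.yaml"))
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort.csv`.
#' @return a list with `features` (matrix) and `labels` (data.frame); the
#'   generating config is re-attached when `config.yaml` is present.
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "cohort.csv")
  if (!file.exists(path))
    stop("no cohort.csv found in ", dir, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  lab_cols <- grep("^label_", names(tab), value = TRUE)
  labels <- tab[lab_cols]
  names(labels) <- sub("^label_", "", lab_cols)
  X <- as.matrix(tab[setdiff(names(tab), lab_cols)])
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  list(features = X, labels = labels, config = cfg)
}
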