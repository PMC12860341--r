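#' Stratified fold assignment
#'
#' Assigns each patient to one of `k` cross-validation folds, stratified by
#' class: positives and negatives are shuffled separately and dealt
#' round-robin, so every fold's positive count is within one of the ideal
#' proportional share.
#'
#' @param y binary 0/1 vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector in `1..k`, class `fold_assignment`, with
#'   attribute `k`.
#' @examples
#' table(stratified_folds(rep(c(0, 1), c(90, 10)), k = 10, seed = 1),
#'       rep(c(0, 1), c(90, 10)))
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  n <- length(y)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of patients", call. = FALSE)
  if (sum(y == 1L) < k)
    warning("fewer positives (", sum(y == 1L), ") than folds (", k,
            "): stratification is degenerate, some training splits may ",
            "lack positives", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cls in c(1L, 0L)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    # rotate the round-robin start so total fold sizes stay within one
    fold[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
    offset <- (offset + length(idx)) %% k
  }
  structure(fold, k = k, class = "fold_assignment")
}
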