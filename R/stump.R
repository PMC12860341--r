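# Weighted shallow trees and discrete AdaBoost.
#
# These are the work-horses of the undersampling ensembles (easy_ensemble,
# rus_boost). The split search is fully vectorised: a "sorted view" of the
# training matrix (per-column order indices and sorted values) is built once
# per ensemble member and filtered — never re-sorted — when the tree
# recurses, and every candidate cut of every feature is scored in a handful
# of matrix operations per boosting round.

# column-wise cumulative sums without a per-column loop
colcumsum <- function(m) {
  n <- nrow(m); p <- ncol(m)
  cs <- matrix(cumsum(m), n, p)
  if (p > 1L)
    cs <- cs - matrix(rep(c(0, cs[n, -p]), each = n), n, p)
  cs
}

# Sorted view: ORD[i, j] is the original row id of the i-th smallest value
# of feature j within the current node; XS holds the sorted values.
sorted_view <- function(X, rows = seq_len(nrow(X))) {
  Xs <- X[rows, , drop = FALSE]
  ORD <- apply(Xs, 2L, order)
  if (is.null(dim(ORD))) ORD <- matrix(ORD, ncol = ncol(X))
  ORD <- matrix(rows[ORD], nrow(ORD), ncol(ORD))
  XS <- matrix(X[cbind(as.vector(ORD),
                       rep(seq_len(ncol(X)), each = nrow(ORD)))],
               nrow(ORD), ncol(ORD))
  list(ORD = ORD, XS = XS, rows = rows, n = length(rows), p = ncol(X))
}

# Filter a view to a subset of its rows (keep: logical over original row
# ids). Filtering preserves sort order, so no re-sorting is needed.
filter_view <- function(view, keep) {
  M <- matrix(keep[view$ORD], view$n, view$p)
  n_child <- sum(keep[view$rows])
  list(ORD = matrix(view$ORD[M], n_child, view$p),
       XS = matrix(view$XS[M], n_child, view$p),
       rows = view$rows[keep[view$rows]], n = n_child, p = view$p)
}

# Best weighted stump within a view. wp/wn: positive/negative class weights
# indexed by original row id (only the view's rows contribute).
#
# With d(cut) = cumulative (wp - wn) left of the cut, the two polarity
# errors are affine in d: left-positive error = Wp - d, left-negative
# error = Wn + d — so one cumsum plus a max and a min scan all cuts of all
# features.
stump_fit_view <- function(view, wp, wn) {
  n <- view$n; p <- view$p
  Wp <- sum(wp[view$rows]); Wn <- sum(wn[view$rows])
  best <- list(feature = 0L, threshold = NA_real_,
               left_pos = Wp >= Wn, right_pos = Wp >= Wn,
               error = min(Wp, Wn))
  if (n < 2L) return(best)
  wd <- wp - wn
  d <- colcumsum(matrix(wd[view$ORD], n, p))[-n, , drop = FALSE]
  invalid <- view$XS[-n, , drop = FALSE] >= view$XS[-1L, , drop = FALSE]
  dmax <- d; dmax[invalid] <- -Inf
  dmin <- d; dmin[invalid] <- Inf
  i1 <- which.max(dmax)       # first extremum: deterministic tie-break
  i2 <- which.min(dmin)
  if (length(i1) && is.finite(dmax[i1]) && Wp - dmax[i1] < best$error) {
    r <- (i1 - 1L) %% (n - 1L) + 1L; cl <- (i1 - 1L) %/% (n - 1L) + 1L
    best <- list(feature = cl,
                 threshold = (view$XS[r, cl] + view$XS[r + 1L, cl]) / 2,
                 left_pos = TRUE, right_pos = FALSE, error = Wp - dmax[i1])
  }
  if (length(i2) && is.finite(dmin[i2]) && Wn + dmin[i2] < best$error) {
    r <- (i2 - 1L) %% (n - 1L) + 1L; cl <- (i2 - 1L) %/% (n - 1L) + 1L
    best <- list(feature = cl,
                 threshold = (view$XS[r, cl] + view$XS[r + 1L, cl]) / 2,
                 left_pos = FALSE, right_pos = TRUE, error = Wn + dmin[i2])
  }
  best
}

# Back-compatible single-matrix interface used by tests and rus_boost.
stump_fit <- function(X, y, w, ord = NULL) {
  view <- sorted_view(as.matrix(X))
  stump_fit_view(view, w * (y == 1L), w * (y == 0L))
}

stump_predict <- function(stump, X) {
  if (stump$feature == 0L)
    return(rep(as.integer(stump$left_pos), nrow(X)))
  ifelse(X[, stump$feature] <= stump$threshold,
         as.integer(stump$left_pos), as.integer(stump$right_pos))
}

# Shallow weighted classification tree grown by recursive stump search.
# Depth 1 is a stump; depth 2 can represent pairwise interactions, which
# matters both for the planted interaction signal and for stage models that
# must combine the stage_prob meta-feature with raw features.
wtree_fit_view <- function(X, y, wp, wn, view, depth) {
  st <- stump_fit_view(view, wp, wn)
  node <- list(stump = st, left = NULL, right = NULL)
  if (st$feature == 0L || depth <= 1L) return(node)
  keep <- logical(nrow(X))
  keep[view$rows[X[view$rows, st$feature] <= st$threshold]] <- TRUE
  for (side in c("left", "right")) {
    rows_side <- if (side == "left") view$rows[keep[view$rows]]
                 else view$rows[!keep[view$rows]]
    if (length(rows_side) >= 4L && length(unique(y[rows_side])) == 2L) {
      child_view <- filter_view(view, if (side == "left") keep else !keep)
      node[[side]] <- wtree_fit_view(X, y, wp, wn, child_view, depth - 1L)
    }
  }
  node
}

wtree_fit <- function(X, y, w, depth, ord = NULL) {
  X <- as.matrix(X)
  wtree_fit_view(X, y, w * (y == 1L), w * (y == 0L), sorted_view(X), depth)
}

# index-based recursion: no feature-matrix copies
wtree_predict_idx <- function(node, X, idx) {
  st <- node$stump
  if (st$feature == 0L)
    return(rep(as.integer(st$left_pos), length(idx)))
  left <- X[idx, st$feature] <= st$threshold
  out <- ifelse(left, as.integer(st$left_pos), as.integer(st$right_pos))
  if (!is.null(node$left) && any(left))
    out[left] <- wtree_predict_idx(node$left, X, idx[left])
  if (!is.null(node$right) && any(!left))
    out[!left] <- wtree_predict_idx(node$right, X, idx[!left])
  out
}

wtree_predict <- function(node, X) {
  wtree_predict_idx(node, X, seq_len(nrow(X)))
}

# Discrete AdaBoost over shallow weighted trees. Returns normalised margin
# scores mapped to [0,1] at predict time:
# p = (1 + sum(alpha * (2h-1)) / sum(alpha)) / 2.
adaboost_fit <- function(X, y, n_rounds = 50L, w = NULL, tree_depth = 2L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1 / n, n)
  if (length(unique(y)) < 2L) {
    return(structure(list(trees = list(), alphas = numeric(0),
                          constant = mean(y)), class = "adaboost"))
  }
  root_view <- sorted_view(X)
  trees <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  idx_all <- seq_len(n)
  for (t in seq_len(n_rounds)) {
    tr <- wtree_fit_view(X, y, w * (y == 1L), w * (y == 0L),
                         root_view, tree_depth)
    h <- wtree_predict_idx(tr, X, idx_all)
    err <- sum(w[h != y]) / sum(w)
    if (err >= 0.5) break
    alpha <- if (err <= 0) 10 else 0.5 * log((1 - err) / err)
    used <- used + 1L
    trees[[used]] <- tr
    alphas[used] <- alpha
    if (err <= 0) break
    w <- w * exp(alpha * (h != y))
    w <- w / sum(w)
  }
  if (used == 0L) {  # no usable weak learner: fall back to prior
    return(structure(list(trees = list(), alphas = numeric(0),
                          constant = mean(y)), class = "adaboost"))
  }
  structure(list(trees = trees[seq_len(used)],
                 alphas = alphas[seq_len(used)], constant = NULL),
            class = "adaboost")
}

adaboost_prob <- function(fit, X) {
  X <- as.matrix(X)
  if (length(fit$alphas) == 0L)
    return(rep(fit$constant, nrow(X)))
  score <- numeric(nrow(X))
  idx <- seq_len(nrow(X))
  for (t in seq_along(fit$alphas))
    score <- score +
      fit$alphas[t] * (2 * wtree_predict_idx(fit$trees[[t]], X, idx) - 1)
  (1 + score / sum(fit$alphas)) / 2
}
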