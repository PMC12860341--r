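#' Per-stage capture accounting
#'
#' Tracks every patient's correctness trajectory across the stage chain
#' (predicted label at the threshold versus truth, per stage) and reduces it
#' to the stage-transition bookkeeping: cases captured at stage 1, cases
#' newly captured at each later stage (wrong at every earlier stage, correct
#' now), cases lost at each stage (correct at some earlier stage, wrong
#' now), and cases never captured — separately for the positive and the
#' negative class. The full trajectory lattice is retained in
#' `$patterns`, so richer transition questions (e.g. cases flipped wrong at
#' stage 2 and recaptured at stage 3) remain answerable.
#'
#' @param stage_oof list of per-stage probability vectors, in stage order.
#' @param y binary 0/1 labels.
#' @param threshold probability cut-off (default 0.5; strictly-greater
#'   positive rule).
#' @return object of class `stage_accounting`: a list with one entry per
#'   class (`positive`, `negative`), each carrying `total`,
#'   `captured_stage1`, `newly_captured` (named vector, stages 2..M),
#'   `lost` (same shape), `never_captured`, `final_correct`; plus
#'   `$patterns` (correctness-pattern counts per class) and `$n_stages`.
#' @examples
#' y <- c(1, 1, 1, 0, 0)
#' s1 <- c(0.9, 0.2, 0.1, 0.1, 0.8)   # captures patient 1 only
#' s2 <- c(0.8, 0.7, 0.2, 0.2, 0.9)   # newly captures patient 2
#' stage_accounting(list(s1, s2), y)
#' @export
stage_accounting <- function(stage_oof, y, threshold = 0.5) {
  if (!length(stage_oof)) stop("at least one stage is required", call. = FALSE)
  y <- as.integer(y)
  lens <- vapply(stage_oof, length, 0L)
  if (any(lens != length(y)))
    stop("stage probabilities and y are not conformable", call. = FALSE)
  M <- length(stage_oof)
  pred <- vapply(stage_oof, classify_probs, integer(length(y)),
                 threshold = threshold)
  if (is.null(dim(pred))) pred <- matrix(pred, ncol = M)
  correct <- pred == y
  out <- list()
  for (cls in c("positive", "negative")) {
    rows <- if (cls == "positive") y == 1L else y == 0L
    C <- correct[rows, , drop = FALSE]
    newly <- lost <- integer(0)
    if (M >= 2L) {
      newly <- lost <- setNames(integer(M - 1L), paste0("stage_", 2:M))
      for (j in 2:M) {
        prior_any <- apply(C[, seq_len(j - 1L), drop = FALSE], 1L, any)
        newly[j - 1L] <- sum(C[, j] & !prior_any)
        lost[j - 1L] <- sum(!C[, j] & prior_any)
      }
    }
    out[[cls]] <- list(total = nrow(C),
                       captured_stage1 = sum(C[, 1L]),
                       newly_captured = newly,
                       lost = lost,
                       never_captured = sum(!apply(C, 1L, any)),
                       final_correct = sum(C[, M]))
  }
  pat <- apply(correct, 1L, function(r) paste(as.integer(r), collapse = ""))
  out$patterns <- table(class = ifelse(y == 1L, "positive", "negative"),
                        pattern = pat)
  out$n_stages <- M
  out$threshold <- threshold
  class(out) <- "stage_accounting"
  out
}

#' @export
print.stage_accounting <- function(x, ...) {
  cat(sprintf("Stage accounting over %d stage(s), cut-off %g\n",
              x$n_stages, x$threshold))
  for (cls in c("positive", "negative")) {
    a <- x[[cls]]
    cat(sprintf("  %s (n=%d): stage 1 captured %d", cls, a$total,
                a$captured_stage1))
    if (length(a$newly_captured))
      cat("; newly captured ",
          paste(sprintf("%s:+%d/-%d", names(a$newly_captured),
                        a$newly_captured, a$lost), collapse = ", "),
          sep = "")
    cat(sprintf("; final correct %d; never %d\n",
                a$final_correct, a$never_captured))
  }
  invisible(x)
}

#' Flatten stage accounting to a delimited-text table
#'
#' @param x a `stage_accounting` object.
#' @return data.frame with one row per class and per-stage count columns.
#' @export
accounting_table <- function(x) {
  stopifnot(inherits(x, "stage_accounting"))
  rows <- lapply(c("positive", "negative"), function(cls) {
    a <- x[[cls]]
    base <- data.frame(class = cls, total = a$total,
                       captured_stage1 = a$captured_stage1,
                       never_captured = a$never_captured,
                       final_correct = a$final_correct)
    if (length(a$newly_captured)) {
      nc <- as.data.frame(as.list(a$newly_captured))
      names(nc) <- paste0("newly_captured_", 2:x$n_stages)
      lo <- as.data.frame(as.list(a$lost))
      names(lo) <- paste0("lost_", 2:x$n_stages)
      base <- cbind(base, nc, lo)
    }
    base
  })
  do.call(rbind, rows)
}
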