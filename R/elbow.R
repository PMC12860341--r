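#' Slope changes along a performance trajectory
#'
#' For a trajectory `p_1..p_M` (here: TPR per stage), the slope change at an
#' interior stage `i` is the absolute difference between the improvement
#' entering the stage and the improvement leaving it:
#' `s_i = |(p_i - p_{i-1}) - (p_{i+1} - p_i)|`, defined for `i = 2..M-1`.
#' A linear trajectory has zero slope change everywhere; the stage where the
#' trajectory bends most is the elbow.
#'
#' @param p numeric trajectory of length >= 3.
#' @return numeric vector `s_2..s_{M-1}` (length `M - 2`), named by stage.
#' @examples
#' slope_changes(c(0.60, 0.873, 0.90, 0.968))
#' @export
slope_changes <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 3L)
    stop("trajectory too short: slope changes need at least 3 stages",
         call. = FALSE)
  if (anyNA(p)) stop("trajectory contains NA", call. = FALSE)
  m <- length(p)
  i <- 2:(m - 1L)
  s <- abs((p[i] - p[i - 1L]) - (p[i + 1L] - p[i]))
  names(s) <- paste0("s", i)
  s
}

#' Select the optimal stage at the elbow
#'
#' Returns the stage whose slope change is maximal; ties break toward the
#' smallest stage (fewer stages, less overfitting risk).
#'
#' @param s slope-change vector from [slope_changes()] (`s[1]` is stage 2).
#' @return integer stage index in `2..(length(s) + 1)`.
#' @examples
#' select_stage(slope_changes(c(0.60, 0.873, 0.90, 0.968)))  # 2
#' @export
select_stage <- function(s) {
  if (length(s) == 0L)
    stop("empty slope-change vector", call. = FALSE)
  if (anyNA(s)) stop("slope changes contain NA", call. = FALSE)
  as.integer(which.max(s) + 1L)
}
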