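# Reward shaping and self-adaptive scalarization. Each objective (predicted
# pIC50, to maximize; synthetic accessibility, to minimize) is mapped to a
# normalized reward in [0, 1] by a clipped sigmoid, combined additively with
# weights w1 + w2 = 1, and the weights are adjusted online: when one
# objective is favoured while the other has plateaued (variation ratio below
# threshold over a five-batch window), weight shifts toward the neglected one.

#' Reward shape for one objective
#'
#' A monotone map from property units to reward in [0, 1]: a sigmoid rescaled
#' so that the reward is exactly 0 at \code{low} and 1 at \code{high} (for a
#' maximized objective; reversed for a minimized one), strictly monotone in
#' between, and pinned outside the saturation points.
#'
#' @param objective \code{"maximize"} or \code{"minimize"}.
#' @param low,high saturation points in property units (low < high).
#' @param steepness sigmoid half-width in units of the [low, high] span.
#' @return an object of class \code{rewardShape}.
#' @examples
#' shapeReward(9, rewardShape("maximize", 4, 9))   # 1
#' shapeReward(1, rewardShape("minimize", 1, 6))   # 1
#' @export
rewardShape <- function(objective = c("maximize", "minimize"), low, high,
                        steepness = 4) {
  objective <- match.arg(objective)
  stopifnot(is.finite(low), is.finite(high), low < high, steepness > 0)
  structure(list(objective = objective, low = low, high = high,
                 steepness = steepness), class = "rewardShape")
}

#' Map property values to normalized rewards
#'
#' @param value numeric property values (finite).
#' @param shape a \code{\link{rewardShape}}.
#' @return rewards in [0, 1], increasing in the property for a maximized
#'   objective and decreasing for a minimized one.
#' @export
shapeReward <- function(value, shape) {
  if (any(is.na(value))) stop("NaN/NA property value in reward shaping")
  mid <- (shape$low + shape$high) / 2
  halfspan <- (shape$high - shape$low) / 2
  g <- function(x) .sigm(shape$steepness * (x - mid) / halfspan)
  s0 <- g(shape$low); s1 <- g(shape$high)
  r <- (g(value) - s0) / (s1 - s0)
  r <- pmin(1, pmax(0, r))
  if (shape$objective == "minimize") r <- 1 - r
  r
}

#' Self-adaptive scalarization state
#'
#' Holds the objective weights (w1 for pIC50, w2 for synthetic accessibility),
#' the recent batch-mean reward history of each objective (a window of at most
#' \code{window} batches), the weight increment and the variation-ratio
#' plateau threshold.
#'
#' @slot w numeric length-2 weights in [0, 1] summing to 1.
#' @slot history list with numeric vectors \code{f1}, \code{f2}.
#' @slot step weight increment per update.
#' @slot vrThreshold plateau threshold on the variation ratio.
#' @slot window history window length.
#' @exportClass ScalarizationState
setClass("ScalarizationState",
  representation(w = "numeric", history = "list", step = "numeric",
                 vrThreshold = "numeric", window = "integer"))

setValidity("ScalarizationState", function(object) {
  msgs <- character()
  if (length(object@w) != 2 || any(object@w < 0) || any(object@w > 1))
    msgs <- c(msgs, "weights must be two values in [0, 1]")
  else if (abs(sum(object@w) - 1) > 1e-9)
    msgs <- c(msgs, "weights must sum to 1")
  if (!all(c("f1", "f2") %in% names(object@history)))
    msgs <- c(msgs, "history must hold f1 and f2")
  if (length(msgs)) msgs else TRUE
})

#' Create a scalarization state
#'
#' @param w initial weights (pIC50, SAS); default c(0.6, 0.4).
#' @param step weight increment per update (default 0.05; the alternative
#'   printed convention 0.1 is available by argument).
#' @param vrThreshold variation-ratio plateau threshold (default 0.05).
#' @param window reward-history window in batches (default 5).
#' @return a \linkS4class{ScalarizationState}.
#' @export
scalarizationState <- function(w = c(0.6, 0.4), step = 0.05,
                               vrThreshold = 0.05, window = 5L) {
  new("ScalarizationState", w = w, history = list(f1 = numeric(0),
                                                  f2 = numeric(0)),
      step = step, vrThreshold = vrThreshold, window = as.integer(window))
}

#' Current objective weights
#' @param state a \linkS4class{ScalarizationState}.
#' @return named numeric c(w1, w2).
#' @export
weightValues <- function(state) c(w1 = state@w[1], w2 = state@w[2])

setMethod("show", "ScalarizationState", function(object) {
  cat(sprintf("ScalarizationState: w = (%.2f, %.2f), step %.2f, VR < %.2f over %d batches\n",
              object@w[1], object@w[2], object@step, object@vrThreshold,
              object@window))
})

#' Scalarize two normalized rewards
#'
#' \eqn{f(x) = w_1 r_1 + w_2 r_2}; linear in each argument and itself in
#' [0, 1].
#'
#' @param r1,r2 rewards in [0, 1].
#' @param state a \linkS4class{ScalarizationState} (or a length-2 weight
#'   vector).
#' @return scalar reward(s).
#' @export
scalarize <- function(r1, r2, state) {
  w <- if (is(state, "ScalarizationState")) state@w else state
  if (length(w) != 2 || any(w < 0) || any(w > 1) || abs(sum(w) - 1) > 1e-9)
    stop("invalid scalarization weights")
  if (any(r1 < -1e-9 | r1 > 1 + 1e-9) || any(r2 < -1e-9 | r2 > 1 + 1e-9))
    stop("rewards must lie in [0, 1]")
  w[1] * r1 + w[2] * r2
}

#' Variation ratio of a reward window
#'
#' Plateau detector: \code{(max - min) / max} over the window (0 for a
#' constant series; NA with fewer than 2 entries, in which case the weight
#' update is skipped). The alternative coefficient-of-variation convention
#' \code{sd/mean} is available via \code{method}.
#'
#' @param history numeric vector of batch-mean rewards (window of <= 5).
#' @param method \code{"range"} (default) or \code{"cv"}.
#' @return non-negative ratio, or NA when undefined.
#' @export
variationRatio <- function(history, method = c("range", "cv")) {
  method <- match.arg(method)
  if (length(history) < 2) return(NA_real_)
  if (method == "cv") {
    m <- mean(history)
    if (m <= 0) return(0)
    return(stats::sd(history) / m)
  }
  mx <- max(history)
  if (mx <= 0) return(0)
  (mx - min(history)) / mx
}

#' Record one batch of objective rewards
#'
#' Appends the batch-mean normalized rewards to the per-objective history,
#' truncating to the window length.
#'
#' @param state a \linkS4class{ScalarizationState}.
#' @param f1,f2 batch-mean rewards in [0, 1].
#' @return the updated state.
#' @export
recordRewards <- function(state, f1, f2) {
  state@history$f1 <- utils::tail(c(state@history$f1, f1), state@window)
  state@history$f2 <- utils::tail(c(state@history$f2, f2), state@window)
  state
}

#' Self-adaptive weight update
#'
#' One application of the adaptation rule: if the first objective is favoured
#' (\eqn{w_1 f_1 > w_2 f_2}) while the second has plateaued
#' (\eqn{VR(f_2) <} threshold), shift weight from the first to the second by
#' \code{step}; symmetrically for the reverse; otherwise leave the weights
#' unchanged. Results are clipped to [0, 1] and re-coupled so the weights sum
#' to 1. With fewer than two recorded batches the update is skipped.
#'
#' @param state a \linkS4class{ScalarizationState} with recorded rewards.
#' @param vrMethod forwarded to \code{\link{variationRatio}}.
#' @return the updated state.
#' @export
updateWeights <- function(state, vrMethod = "range") {
  h1 <- state@history$f1
  h2 <- state@history$f2
  if (!length(h1) || !length(h2)) return(state)
  f1 <- h1[length(h1)]
  f2 <- h2[length(h2)]
  vr1 <- variationRatio(h1, vrMethod)
  vr2 <- variationRatio(h2, vrMethod)
  w1 <- state@w[1]; w2 <- state@w[2]
  eps <- 1e-9  # guards against float ties flip-flopping at the balance point
  if (!is.na(vr2) && w1 * f1 > w2 * f2 + eps && vr2 < state@vrThreshold) {
    w1 <- w1 - state@step
  } else if (!is.na(vr1) && w1 * f1 + eps < w2 * f2 && vr1 < state@vrThreshold) {
    w1 <- w1 + state@step
  } else {
    return(state)
  }
  w1 <- min(1, max(0, w1))
  state@w <- c(w1, 1 - w1)
  state
}

#' Default two-objective reward configuration
#'
#' Clipped-sigmoid shapes (pIC50 rising 0 to 1 over [4, 9]; SAS falling 1 to 0
#' over [1, 6]) and a scalarization state initialized at weights (0.6, 0.4),
#' step 0.05, variation-ratio threshold 0.05, window 5.
#'
#' @param pic50Low,pic50High,sasLow,sasHigh saturation points.
#' @param w,step,vrThreshold,window forwarded to
#'   \code{\link{scalarizationState}}.
#' @return list with \code{pic50} and \code{sas} shapes and \code{state}.
#' @export
defaultRewardConfig <- function(pic50Low = 4, pic50High = 9, sasLow = 1,
                                sasHigh = 6, w = c(0.6, 0.4), step = 0.05,
                                vrThreshold = 0.05, window = 5L) {
  list(pic50 = rewardShape("maximize", pic50Low, pic50High),
       sas = rewardShape("minimize", sasLow, sasHigh),
       state = scalarizationState(w, step, vrThreshold, window))
}
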