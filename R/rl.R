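# REINFORCE fine-tuning of the SMILES generator. Each sampled molecule
# receives one terminal scalar reward (scalarized pIC50/SAS; 0 for invalid
# strings), distributed over its emitted tokens as discounted returns; the
# policy-gradient step descends on
#   loss = -(1/B) sum_b sum_t gamma^t R_t ln pi(A_t | S_t),
# whose gradient realizes the classic score-function ascent.

#' Discounted returns of a reward trace
#'
#' \eqn{R_t = \sum_{k \ge 0} \gamma^k r_{t+k}} computed right-to-left, where
#' \code{rewards[t]} is the reward received after the t-th action.
#'
#' @param rewards numeric vector of per-step rewards (finite).
#' @param gamma discount factor in [0, 1].
#' @return numeric vector of returns, same length.
#' @examples
#' discountedReturns(c(0, 0, 1), 0.5)  # 0.25 0.50 1.00
#' @export
discountedReturns <- function(rewards, gamma = 1) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (any(!is.finite(rewards))) stop("rewards must be finite")
  n <- length(rewards)
  out <- numeric(n)
  acc <- 0
  for (t in rev(seq_len(n))) {
    acc <- rewards[t] + gamma * acc
    out[t] <- acc
  }
  out
}

#' Build a REINFORCE trajectory
#'
#' @param actions integer or character action sequence.
#' @param terminalReward scalar reward granted after the final action.
#' @param logProbs per-step log-probabilities of the actions under the
#'   current policy.
#' @param gamma discount factor.
#' @return list with \code{actions}, \code{rewards} (terminal-only trace),
#'   \code{returns}, \code{logProbs}.
#' @export
makeTrajectory <- function(actions, terminalReward, logProbs, gamma = 1) {
  T_ <- length(actions)
  stopifnot(length(logProbs) == T_)
  rewards <- c(rep(0, T_ - 1L), terminalReward)
  list(actions = actions, rewards = rewards,
       returns = discountedReturns(rewards, gamma), logProbs = logProbs)
}

#' REINFORCE loss of a trajectory batch
#'
#' \eqn{-(1/B)\sum_b \sum_t \gamma^t R_t \ln \pi(A_t|S_t)}. Zero rewards give
#' zero loss (and zero gradient); the loss is linear in the rewards.
#'
#' @param trajectories list of trajectories from \code{\link{makeTrajectory}}.
#' @param gamma discount factor used for the \eqn{\gamma^t} step weighting.
#' @return scalar loss.
#' @export
reinforceLoss <- function(trajectories, gamma = 1) {
  if (!length(trajectories)) stop("empty trajectory batch")
  total <- vapply(trajectories, function(tr) {
    T_ <- length(tr$actions)
    -sum(gamma^(seq_len(T_) - 1L) * tr$returns * tr$logProbs)
  }, numeric(1))
  mean(total)
}

#' Gradient of the REINFORCE loss with respect to policy logits
#'
#' For a categorical policy \eqn{\pi = \mathrm{softmax}(z)} and loss
#' \eqn{-\sum_b w_b \ln \pi(a_b)}, the exact logit gradient is
#' \eqn{w_b(\pi - e_{a_b})} per row. This is the kernel the policy update in
#' \code{\link{rlEpoch}} backpropagates through the generator.
#'
#' @param probs B x V matrix of action probabilities.
#' @param actions length-B integer actions (1-based).
#' @param weights length-B step weights (e.g. \eqn{\gamma^t R_t / B}).
#' @return B x V gradient matrix.
#' @export
reinforceLogitGradient <- function(probs, actions, weights) {
  .softmaxCEGrad(probs, actions, weights)$dlogits
}

#' Reinforcement-learning configuration
#'
#' @param epochs optimization epochs (default 90).
#' @param batchSize molecules sampled per epoch.
#' @param learningRate Adam learning rate for the policy update.
#' @param gamma discount factor (default 1: undiscounted terminal reward).
#' @param temperature sampling softmax temperature (default 0.80).
#' @param baseline subtract a moving-average reward baseline (default FALSE,
#'   plain REINFORCE).
#' @param clipNorm global gradient-norm clip.
#' @return named list.
#' @export
rlConfig <- function(epochs = 90L, batchSize = 64L, learningRate = 5e-4,
                     gamma = 1, temperature = 0.80, baseline = FALSE,
                     clipNorm = 5) {
  stopifnot(gamma >= 0, gamma <= 1, temperature > 0)
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       learningRate = learningRate, gamma = gamma, temperature = temperature,
       baseline = baseline, clipNorm = clipNorm)
}

# score one batch of sampled SMILES: validity, properties, shaped rewards
.scoreBatch <- function(smiles, predictor, rewardCfg) {
  n <- length(smiles)
  valid <- logical(n)
  canon <- rep(NA_character_, n)
  nonempty <- nzchar(smiles)   # zero-token samples are invalid by definition
  if (any(nonempty)) {
    rec <- canonicalizeSmiles(smiles[nonempty])
    valid[nonempty] <- rec$valid
    canon[nonempty] <- rec$smiles_canonical
  }
  r1 <- r2 <- numeric(n)
  pic50 <- sas <- rep(NA_real_, n)
  vidx <- which(valid)
  if (length(vidx)) {
    can <- canon[vidx]
    pv <- predictPic50(predictor, can)$pic50
    sv <- syntheticAccessibility(can)
    okprop <- !is.na(pv) & !is.na(sv)
    pic50[vidx] <- pv
    sas[vidx] <- sv
    r1[vidx[okprop]] <- shapeReward(pv[okprop], rewardCfg$pic50)
    r2[vidx[okprop]] <- shapeReward(sv[okprop], rewardCfg$sas)
  }
  list(valid = valid, pic50 = pic50, sas = sas, r1 = r1, r2 = r2)
}

#' One REINFORCE epoch
#'
#' Samples a batch at the configured temperature, validates and scores it
#' (predicted pIC50 and synthetic accessibility; invalid strings get reward 0
#' on both objectives), scalarizes with the current weights, applies one
#' self-adaptive weight update, and takes one clipped Adam policy-gradient
#' step. An all-invalid batch skips the gradient step with a warning.
#'
#' @param generator a \linkS4class{SmilesGenerator}.
#' @param predictor a trained \linkS4class{Pic50Predictor}.
#' @param rewardCfg list from \code{\link{defaultRewardConfig}}.
#' @param config list from \code{\link{rlConfig}}.
#' @param seed integer seed for the batch.
#' @param optState optimizer state (created when NULL; pass back between
#'   epochs).
#' @return list with updated \code{generator}, \code{state}, \code{optState}
#'   and a one-row \code{report} (weights, mean rewards, validity).
#' @export
rlEpoch <- function(generator, predictor, rewardCfg, config = rlConfig(),
                    seed = 1L, optState = NULL) {
  smiles <- sampleSmiles(generator, config$batchSize,
                         temperature = config$temperature, seed = seed)
  score <- .scoreBatch(smiles, predictor, rewardCfg)
  state <- rewardCfg$state
  f1 <- mean(score$r1)
  f2 <- mean(score$r2)
  w <- state@w
  scalar <- scalarize(score$r1, score$r2, state)
  state <- recordRewards(state, f1, f2)
  state <- updateWeights(state)
  rewardCfg$state <- state
  report <- data.frame(w1 = w[1], w2 = w[2], mean_r1 = f1, mean_r2 = f2,
                       mean_scalar = mean(scalar),
                       validity = mean(score$valid))
  nonempty <- nzchar(smiles)
  if (!any(score$valid) || !any(nonempty)) {
    warning("all sampled molecules invalid; gradient step skipped")
    return(list(generator = generator, rewardCfg = rewardCfg,
                optState = optState, report = report))
  }
  if (is.null(optState))
    optState <- .adamInit(generator@params)
  if (config$baseline) {
    scalar <- scalar - mean(scalar)
  }
  vocab <- generator@vocab
  toks <- lapply(smiles[nonempty], tokenizeSmiles, vocab = vocab)
  scalar <- scalar[nonempty]
  lens <- lengths(toks)
  eosId <- tokenIndex(vocab, vocab@specials[["EOS"]]) + 1L
  goId <- tokenIndex(vocab, vocab@specials[["GO"]]) + 1L
  padId <- 1L
  B <- length(toks)
  Tmax <- max(lens) + 1L  # payload + EOS action
  Xin <- matrix(padId, B, Tmax)
  Tgt <- matrix(padId, B, Tmax)
  Wt <- matrix(0, B, Tmax)
  for (b in seq_len(B)) {
    codes <- tokenIndex(vocab, toks[[b]]) + 1L
    T_b <- lens[b] + 1L
    Xin[b, seq_len(T_b)] <- c(goId, codes)
    Tgt[b, seq_len(T_b)] <- c(codes, eosId)
    # terminal-only reward: R_t = gamma^(T-t) * r; step weight gamma^t R_t
    rets <- discountedReturns(c(rep(0, T_b - 1L), scalar[b]), config$gamma)
    Wt[b, seq_len(T_b)] <- config$gamma^(seq_len(T_b) - 1L) * rets / B
  }
  fwd <- .lstmForward(generator@params, Xin)
  dlog <- vector("list", Tmax)
  loss <- 0
  for (t in seq_len(Tmax)) {
    ce <- .softmaxCEGrad(fwd$probs[[t]], Tgt[, t], Wt[, t])
    loss <- loss + ce$loss
    dlog[[t]] <- ce$dlogits
  }
  grads <- .clipByNorm(.lstmBackward(generator@params, Xin, fwd, dlog),
                       config$clipNorm)
  generator@params <- .adamStep(generator@params, grads, optState,
                                config$learningRate)
  report$loss <- loss
  list(generator = generator, rewardCfg = rewardCfg, optState = optState,
       report = report)
}

#' Run the full conditioned-generation optimization
#'
#' Loops \code{\link{rlEpoch}} for the configured number of epochs, logging
#' weights, mean per-objective rewards, mean scalarized reward and validity
#' per epoch.
#'
#' @param generator pre-trained \linkS4class{SmilesGenerator}.
#' @param predictor trained \linkS4class{Pic50Predictor}.
#' @param config list from \code{\link{rlConfig}}.
#' @param rewardCfg list from \code{\link{defaultRewardConfig}}.
#' @param seed integer seed (epoch b uses seed + b).
#' @param verbose print a line per epoch.
#' @return list with the biased \code{generator}, the final \code{rewardCfg}
#'   and \code{log}, a data.frame with one row per epoch.
#' @export
runOptimization <- function(generator, predictor, config = rlConfig(),
                            rewardCfg = defaultRewardConfig(), seed = 1L,
                            verbose = FALSE) {
  log <- NULL
  optState <- NULL
  if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
    res <- rlEpoch(generator, predictor, rewardCfg, config,
                   seed = seed + ep, optState = optState)
    generator <- res$generator
    rewardCfg <- res$rewardCfg
    optState <- res$optState
    row <- cbind(epoch = ep, res$report)
    log <- rbind(log, row)
    if (verbose)
      message(sprintf("epoch %2d  w=(%.2f,%.2f)  r1 %.3f  r2 %.3f  valid %.2f",
                      ep, row$w1, row$w2, row$mean_r1, row$mean_r2,
                      row$validity))
  }
  list(generator = generator, rewardCfg = rewardCfg, log = log)
}
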