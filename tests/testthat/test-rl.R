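test_that("discounted returns follow the recursive definition", {
  expect_equal(discountedReturns(c(0, 0, 2), 1), c(2, 2, 2))
  expect_equal(discountedReturns(c(0, 0, 1), 0.5), c(0.25, 0.5, 1))
  r <- c(0.3, 0.1, 0.7)
  expect_equal(discountedReturns(r, 0), r)
  set.seed(2)
  for (i in 1:10) {
    rr <- rnorm(6); g <- runif(1)
    R <- discountedReturns(rr, g)
    for (t in 1:5) expect_equal(R[t], rr[t] + g * R[t + 1])
  }
  expect_error(discountedReturns(1, 1.5), "gamma")
  expect_error(discountedReturns(NaN, 1))
})

test_that("REINFORCE loss is zero for zero reward and linear in rewards", {
  tr <- function(r) makeTrajectory(c(1L, 2L, 1L), r, log(c(0.5, 0.3, 0.2)))
  expect_equal(reinforceLoss(list(tr(0))), 0)
  l1 <- reinforceLoss(list(tr(1)))
  expect_equal(reinforceLoss(list(tr(2))), 2 * l1)
  expect_gt(l1, 0)  # maximizing reward means positive loss on positive reward
  expect_error(reinforceLoss(list()), "empty")
  # gradient kernel: zero weights give a zero gradient
  probs <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE)
  g0 <- reinforceLogitGradient(probs, c(1L, 2L), c(0, 0))
  expect_equal(max(abs(g0)), 0)
})

test_that("analytic score-function gradient matches finite differences", {
  # 2-action single-step bandit, exact expectation over both actions
  theta <- c(0.3, -0.2)
  rewards <- c(1, 0)
  expectedRewardGrad <- function(th) {
    p <- exp(th) / sum(exp(th))
    J <- sum(p * rewards)
    eps <- 1e-6
    g <- numeric(2)
    for (k in 1:2) {
      up <- th; up[k] <- up[k] + eps
      dn <- th; dn[k] <- dn[k] - eps
      Ju <- sum(exp(up) / sum(exp(up)) * rewards)
      Jd <- sum(exp(dn) / sum(exp(dn)) * rewards)
      g[k] <- (Ju - Jd) / (2 * eps)
    }
    list(J = J, grad = g)
  }
  p <- exp(theta) / sum(exp(theta))
  probs <- matrix(p, 1)
  # E[grad] = sum_a pi_a * r_a * d(log pi_a)/dtheta; the loss kernel returns
  # the descent direction, so the ascent gradient is its negation
  analytic <- -(reinforceLogitGradient(probs, 1L, p[1] * rewards[1]) +
                reinforceLogitGradient(probs, 2L, p[2] * rewards[2]))
  fd <- expectedRewardGrad(theta)
  expect_lt(max(abs(as.vector(analytic) - fd$grad)) /
              max(abs(fd$grad)), 1e-4)
})

test_that("policy gradient solves a 3-armed bandit", {
  set.seed(7)
  theta <- c(0, 0, 0)
  rewards <- c(1, 0.5, 0)
  lr <- 0.05
  for (i in 1:2000) {
    p <- exp(theta) / sum(exp(theta))
    a <- sample.int(3L, 1L, prob = p)
    g <- reinforceLogitGradient(matrix(p, 1), a, rewards[a])
    theta <- theta - lr * as.vector(g)
  }
  p <- exp(theta) / sum(exp(theta))
  expect_gt(p[1], 0.9)
})

test_that("an RL epoch is deterministic and inert at zero learning rate", {
  gen <- tinyGenerator()
  pred <- tinyPredictor()
  rc <- defaultRewardConfig()
  cfg0 <- rlConfig(batchSize = 12L, learningRate = 0, temperature = 0.9)
  r1 <- suppressWarnings(rlEpoch(gen, pred, rc, cfg0, seed = 21))
  expect_lt(relErr(r1$generator@params, gen@params), 1e-12)
  cfg <- rlConfig(batchSize = 12L, learningRate = 1e-3, temperature = 0.9)
  a <- suppressWarnings(rlEpoch(gen, pred, rc, cfg, seed = 33))
  b <- suppressWarnings(rlEpoch(gen, pred, rc, cfg, seed = 33))
  expect_identical(a$report, b$report)
  expect_lt(relErr(a$generator@params, b$generator@params), 1e-12)
  # the weight log stays inside the unit square
  expect_true(all(c(a$report$w1, a$report$w2) >= 0 &
                  c(a$report$w1, a$report$w2) <= 1))
})

test_that("zero-epoch optimization returns the generator unchanged", {
  gen <- tinyGenerator()
  pred <- tinyPredictor()
  out <- runOptimization(gen, pred, rlConfig(epochs = 0L), seed = 4)
  expect_identical(out$generator@params, gen@params)
  expect_null(out$log)
})
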