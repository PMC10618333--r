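# The compiled recurrent kernels are validated two ways: against the plain-R
# reference implementations and against central finite differences.

test_that("compiled LSTM matches the R reference and numerical gradients", {
  set.seed(42)
  V <- 7L; E <- 5L; U <- 6L; B <- 3L; T_ <- 4L
  p <- HitGen:::.lstmInitParams(V, E, U, 2L)
  Xin <- matrix(sample(1:V, B * T_, TRUE), B, T_)
  Tgt <- matrix(sample(1:V, B * T_, TRUE), B, T_)
  W <- matrix(runif(B * T_, 0.2, 1), B, T_)
  fR <- HitGen:::.lstmForwardR(p, Xin)
  fC <- HitGen:::.lstmForward(p, Xin)
  expect_lt(relErr(fR$probs, fC$probs), 1e-12)
  dlog <- lapply(seq_len(T_), function(t)
    HitGen:::.softmaxCEGrad(fC$probs[[t]], Tgt[, t], W[, t])$dlogits)
  gR <- HitGen:::.lstmBackwardR(p, Xin, fR, dlog)
  gC <- HitGen:::.lstmBackward(p, Xin, fC, dlog)
  expect_lt(relErr(gR, gC), 1e-10)
  lossFn <- function(par) {
    f <- HitGen:::.lstmForwardR(par, Xin)
    s <- 0
    for (t in seq_len(T_))
      s <- s + HitGen:::.softmaxCEGrad(f$probs[[t]], Tgt[, t], W[, t])$loss
    s
  }
  ng <- HitGen:::.numericGradient(lossFn, p)
  expect_lt(relErr(gC, ng), 1e-3)
})

test_that("compiled GRU matches the R reference and numerical gradients", {
  set.seed(9)
  B <- 3L; T_ <- 5L; D <- 4L; U <- 3L
  p <- HitGen:::.gruInitParams(D, U)
  xs <- lapply(seq_len(T_), function(t) matrix(rnorm(B * D), B, D))
  fR <- HitGen:::.gruForwardR(p, xs)
  fC <- HitGen:::.gruForward(p, xs)
  expect_lt(relErr(fR$hs, fC$hs), 1e-12)
  dhs <- lapply(seq_len(T_), function(t) matrix(rnorm(B * U) / 10, B, U))
  bR <- HitGen:::.gruBackwardR(p, fR, dhs)
  bC <- HitGen:::.gruBackward(p, fC, dhs)
  expect_lt(relErr(bR$grads, bC$grads), 1e-10)
  expect_lt(relErr(bR$dxs, bC$dxs), 1e-10)
  # gradient of sum(hs * dhs) by finite differences
  lossFn <- function(par) {
    f <- HitGen:::.gruForwardR(par, xs)
    sum(mapply(function(h, d) sum(h * d), f$hs, dhs))
  }
  ng <- HitGen:::.numericGradient(lossFn, p)
  expect_lt(relErr(bC$grads, ng), 1e-4)
})

test_that("softmax rows are proper distributions at every step", {
  set.seed(3)
  z <- matrix(rnorm(40, sd = 8), 5, 8)
  p <- HitGen:::.softmaxRows(z)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("gradient clipping preserves direction and caps the global norm", {
  g <- list(a = matrix(3, 2, 2), b = rep(4, 3))
  clipped <- HitGen:::.clipByNorm(g, 1)
  expect_equal(sqrt(HitGen:::.treeSumSq(clipped)), 1, tolerance = 1e-12)
  expect_equal(clipped$a / clipped$b[1], g$a / g$b[1])
  small <- HitGen:::.clipByNorm(g, 100)
  expect_identical(small, g)
})
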