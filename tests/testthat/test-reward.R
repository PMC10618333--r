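test_that("reward shapes pin the saturation points and stay monotone", {
  sasShape <- rewardShape("minimize", 1, 6)
  expect_equal(shapeReward(1, sasShape), 1)
  expect_equal(shapeReward(10, sasShape), 0)
  picShape <- rewardShape("maximize", 4, 9)
  expect_equal(shapeReward(3, picShape), 0)
  expect_equal(shapeReward(9, picShape), 1)
  xs <- seq(-1e6, 1e6, length.out = 101)
  r <- shapeReward(xs, picShape)
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(diff(shapeReward(seq(4, 9, 0.1), picShape)) > 0))
  expect_true(all(diff(r) >= 0))
  expect_error(shapeReward(NaN, picShape))
})

test_that("scalarization is the weighted sum with valid weights", {
  st <- scalarizationState(c(0.5, 0.5))
  expect_equal(scalarize(0.4, 0.8, st), 0.6)
  expect_equal(scalarize(0.3, 0.9, c(1, 0)), 0.3)
  expect_error(scalarize(0.5, 0.5, c(0.7, 0.7)), "weights")
  expect_error(scalarize(1.5, 0.5, st), "0, 1")
  # default initial preference
  expect_equal(unname(weightValues(scalarizationState())), c(0.6, 0.4))
})

test_that("variation ratio detects plateaus under the range convention", {
  expect_equal(variationRatio(rep(0.5, 5)), 0)
  expect_equal(variationRatio(c(0.50, 0.51)), 0.01 / 0.51, tolerance = 1e-12)
  expect_lt(variationRatio(c(0.50, 0.51)), 0.05)
  expect_equal(variationRatio(c(0.2, 0.4)), 0.5)
  expect_true(is.na(variationRatio(0.7)))
  expect_equal(variationRatio(c(0, 0)), 0)
})

test_that("weight updates fire exactly under their printed conditions", {
  # favoured objective 1 with plateaued objective 2 -> shift toward 2
  st <- scalarizationState(c(0.6, 0.4), step = 0.1)
  st <- recordRewards(st, 0.9, 0.50)
  st <- recordRewards(st, 0.9, 0.505)
  expect_lt(variationRatio(st@history$f2), 0.05)
  st2 <- updateWeights(st)
  expect_equal(unname(st2@w), c(0.5, 0.5))
  # mirrored branch
  st <- scalarizationState(c(0.4, 0.6), step = 0.1)
  st <- recordRewards(st, 0.30, 0.9)
  st <- recordRewards(st, 0.301, 0.9)
  st2 <- updateWeights(st)
  expect_equal(unname(st2@w), c(0.5, 0.5))
  # both objectives still moving -> no branch fires
  st <- scalarizationState(c(0.6, 0.4))
  st <- recordRewards(st, 0.2, 0.2)
  st <- recordRewards(st, 0.9, 0.9)
  expect_identical(updateWeights(st)@w, c(0.6, 0.4))
  # single batch -> undefined VR, update skipped
  st <- recordRewards(scalarizationState(), 0.9, 0.1)
  expect_identical(updateWeights(st)@w, c(0.6, 0.4))
})

test_that("weights stay coupled and clipped through long update sequences", {
  st <- scalarizationState(c(0.1, 0.9), step = 0.2)
  st <- recordRewards(st, 0.9, 0.2)
  st <- recordRewards(st, 0.9, 0.2)
  st <- updateWeights(st)  # pushes w1 below 0
  expect_true(all(st@w >= 0 & st@w <= 1))
  expect_equal(sum(st@w), 1)
  set.seed(1)
  st <- scalarizationState()
  for (i in 1:500) {
    st <- recordRewards(st, runif(1), runif(1))
    st <- updateWeights(st)
    expect_true(all(st@w >= 0 & st@w <= 1))
    expect_equal(sum(st@w), 1, tolerance = 1e-12)
  }
})

test_that("constant rewards extinguish the update trigger (no oscillation)", {
  st <- scalarizationState(c(0.9, 0.1), step = 0.1)
  f1 <- 0.8; f2 <- 0.8
  changes <- 0
  for (i in 1:50) {
    st <- recordRewards(st, f1, f2)
    w0 <- st@w
    st <- updateWeights(st)
    if (!identical(w0, st@w)) changes <- changes + 1
  }
  bound <- ceiling(abs(0.9 * f1 - 0.1 * f2) / (0.1 * (f1 + f2))) + 1
  expect_lte(changes, bound)
  # after extinction the weights sit at the balance point
  expect_lt(abs(st@w[1] * f1 - st@w[2] * f2), 0.1 * (f1 + f2))
})
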