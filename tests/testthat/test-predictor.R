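test_that("IQR label standardization uses type-7 quartiles and inverts", {
  y <- c(5, 6, 7, 8, 9)
  std <- standardizeLabels(y)
  expect_equal(std$scaler$median, 7)
  expect_equal(std$scaler$iqr, 2)
  expect_equal((8 - std$scaler$median) / std$scaler$iqr, 0.5)
  expect_equal(std$z[y == 7], 0)
  set.seed(4)
  yr <- rnorm(40)
  s2 <- standardizeLabels(yr)
  expect_equal(invertLabels(s2$scaler, s2$z), yr, tolerance = 1e-12)
  expect_error(standardizeLabels(rep(3, 10)), "degenerate")
  expect_error(standardizeLabels(c(1, 2)), "at least 4")
})

test_that("attention pooling is a convex combination of hidden states", {
  h1 <- matrix(rnorm(6), 1)
  a1 <- attentionPool(h1)
  expect_equal(a1$alphas, 1)
  expect_equal(a1$context, as.vector(h1))
  # equal alignment scores pool to the plain mean
  H <- matrix(rnorm(4 * 6), 4, 6)
  aeq <- attentionPool(H, query = rep(0, 6), bias = 0.3)
  expect_equal(aeq$alphas, rep(0.25, 4))
  expect_equal(aeq$context, colMeans(H), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    H <- matrix(rnorm(5 * 4), 5, 4)
    a <- attentionPool(H, query = rnorm(4), bias = rnorm(1))
    expect_true(all(a$alphas >= 0))
    expect_equal(sum(a$alphas), 1, tolerance = 1e-6)
    expect_equal(a$context, colSums(a$alphas * H), tolerance = 1e-12)
  }
  expect_error(attentionPool(matrix(numeric(0), 0, 3)))
})

test_that("regression metrics satisfy their identities", {
  y <- c(1, 2, 3, 4)
  m <- regressionMetrics(y, y)
  expect_equal(m$mse, 0); expect_equal(m$q2, 1); expect_equal(m$ccc, 1)
  m0 <- regressionMetrics(y, rep(mean(y), 4))
  expect_equal(m0$q2, 0)
  # hand evaluation of the concordance closed form
  y <- c(1, 2, 3); yh <- c(1, 2, 4)
  vy <- mean((y - mean(y))^2); vh <- mean((yh - mean(yh))^2)
  cv <- mean((y - mean(y)) * (yh - mean(yh)))
  cccHand <- 2 * cv / (vy + vh + (mean(y) - mean(yh))^2)
  expect_equal(regressionMetrics(y, yh)$ccc, cccHand, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    m <- regressionMetrics(a, b)
    expect_lte(m$q2, 1)
    expect_true(m$ccc >= -1 && m$ccc <= 1)
    expect_equal(m$rmse^2, m$mse, tolerance = 1e-10)
  }
  expect_error(regressionMetrics(1:3, 1:4), "mismatch")
})

test_that("every architecture's analytic gradient matches finite differences", {
  set.seed(7)
  for (m in c("A", "D", "E", "F", "G", "H", "I", "J")) {
    cfg <- predictorConfig(m, embeddingDim = 5, units = 4, dropout = 0,
                           denseUnits = c(6, 4), fpBits = 16)
    if (cfg$architecture == "mlp") {
      p <- HitGen:::.predInitParams(cfg, 0L)
      X <- matrix(rbinom(3 * 16, 1, 0.3), 3, 16)
      y <- rnorm(3)
      fwd <- HitGen:::.predForwardMlp(p, X)
      gr <- HitGen:::.predBackwardMlp(p, fwd, 2 * (fwd$pred - y))
      ng <- HitGen:::.numericGradient(function(par)
        sum((HitGen:::.predForwardMlp(par, X)$pred - y)^2), p)
    } else {
      p <- HitGen:::.predInitParams(cfg, 20L)
      X <- matrix(sample(2:19, 3 * 6, TRUE), 3, 6)
      y <- rnorm(3)
      fwd <- HitGen:::.predForwardSeq(p, cfg, X)
      gr <- HitGen:::.predBackwardSeq(p, cfg, X, fwd, 2 * (fwd$pred - y))
      ng <- HitGen:::.numericGradient(function(par)
        sum((HitGen:::.predForwardSeq(par, cfg, X)$pred - y)^2), p)
    }
    expect_lt(relErr(gr, ng), 1e-3)
  }
})

test_that("the configuration table pairs descriptors and architectures legally", {
  expect_identical(predictorConfig("A")$descriptor, "ECFP4")
  expect_identical(predictorConfig("C")$descriptor, "path")
  expect_true(predictorConfig("I")$attention)
  expect_false(predictorConfig("H")$attention)
  expect_identical(predictorConfig("J")$architecture, "sep_birnn")
  expect_error(predictorConfig("K"))
  # attention never appears with fingerprint descriptors
  for (m in c("A", "B", "C")) expect_false(predictorConfig(m)$attention)
})

test_that("training recovers a token-count signal and honors contracts", {
  pred <- tinyPredictor()
  hold <- predictorMetrics(pred)$holdout
  expect_gt(hold$q2, 0.5)
  # canonicalize-before-predict: two spellings, one prediction
  p <- predictPic50(pred, c("OCC", "CCO", "C("))
  expect_equal(p$pic50[1], p$pic50[2], tolerance = 1e-10)
  expect_false(p$valid[3])
  expect_true(is.na(p$pic50[3]))
  # batch equals per-item
  smis <- tinyAffinity(300)$smiles[1:6]
  batch <- predictPic50(pred, smis)$pic50
  single <- vapply(smis, function(s) predictPic50(pred, s)$pic50, numeric(1))
  expect_equal(batch, unname(single), tolerance = 1e-10)
  # attention weights align with the token sequence
  aw <- attentionWeights(pred, smis[1])
  expect_length(aw$alphas, length(aw$tokens))
  expect_equal(sum(aw$alphas), 1, tolerance = 1e-6)
})

test_that("training is seed-deterministic and drops duplicates", {
  tab <- tinyAffinity(300)[1:120, ]
  cfg <- predictorConfig("D", embeddingDim = 16, units = 16, dropout = 0,
                         epochs = 3, patience = 3)
  m1 <- trainPredictor(tab, cfg, seed = 6, cvFolds = 0)
  m2 <- trainPredictor(tab, cfg, seed = 6, cvFolds = 0)
  expect_lt(relErr(m1@params, m2@params), 1e-12)
  # duplicated rows do not enter twice
  dup <- rbind(tab, tab)
  m3 <- trainPredictor(dup, cfg, seed = 6, cvFolds = 0)
  expect_true(is(m3, "Pic50Predictor"))
})

test_that("fine-tuning is the identity at zero epochs and tracks shifts", {
  pred <- tinyPredictor()
  sub <- tinyAffinity(300)[1:60, ]
  expect_identical(fineTune(pred, sub, epochs = 0L), pred)
  shifted <- sub
  shifted$pic50 <- shifted$pic50 + 1
  before <- mean(predictPic50(pred, sub$smiles)$pic50)
  ft <- fineTune(pred, shifted, epochs = 6L, seed = 2)
  after <- mean(predictPic50(ft, sub$smiles)$pic50)
  expect_gt(after, before)
  expect_error(fineTune(pred, sub[0, ], epochs = 2L), "empty")
})
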