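test_that("validity is the share passing the canonicalization oracle", {
  expect_equal(validity(c("CCO", "c1ccccc1", "C(")), 2 / 3)
  expect_equal(validity(c("CCO", "CCN")), 1)
  expect_equal(validity(c("C(", ")(")), 0)
  expect_error(validity(character(0)), "empty")
})

test_that("uniqueness and novelty compare canonical forms", {
  corpus <- c("CCO", "CCN")
  un <- uniquenessNovelty(rep("CCO", 10), corpus)
  expect_equal(un$uniqueness, 0.1)
  expect_equal(un$novelty, 0)
  un2 <- uniquenessNovelty(c("CCCC", "CCCCC"), corpus)
  expect_equal(un2$uniqueness, 1)
  expect_equal(un2$novelty, 1)
  # alternative spelling collides with the training molecule
  un3 <- uniquenessNovelty("OCC", corpus)
  expect_equal(un3$novelty, 0)
  # all-invalid sample is flagged, not crashed
  un4 <- uniquenessNovelty(c("C(", "(("), corpus)
  expect_true(is.na(un4$uniqueness))
  # a corpus is never novel against itself
  expect_equal(uniquenessNovelty(corpus, corpus)$novelty, 0)
})

test_that("diversity agrees with the brute-force pairwise mean", {
  expect_equal(diversity(rep("CCO", 5)), 0)  # identical set collapses
  corpus <- tinyCorpus(300)
  set.seed(6)
  sm <- sample(corpus, 30)
  d <- diversity(sm)
  fps <- lapply(sm, ecfp)
  sims <- c()
  for (i in 1:29) for (j in (i + 1):30)
    sims <- c(sims, tanimoto(fps[[i]], fps[[j]]))
  expect_equal(d, 1 - mean(sims), tolerance = 1e-10)
  # sample inside the reference: external diversity collapses to 0
  expect_equal(diversity(sm, reference = corpus), 0)
  expect_error(diversity("CCO"), ">= 2")
})

test_that("the KLD score is 1 for matching sets and penalizes shifts", {
  corpus <- tinyCorpus(300)
  same <- kldScore(corpus, corpus)
  expect_gt(same$score, 0.95)
  expect_true(all(same$kl >= 0))
  # a heavily halogenated set against the mixed corpus scores clearly lower
  halo <- grep("Cl|Br|F", corpus, value = TRUE)
  skew <- kldScore(rep(halo, length.out = 150), corpus, minN = 100)
  expect_lt(skew$score, same$score)
  expect_true(skew$score >= 0 && skew$score <= 1)
  # direction is fixed: reversing the arguments changes the estimate
  rev_ <- kldScore(corpus, rep(halo, length.out = 150), minN = 100)
  expect_false(isTRUE(all.equal(skew$score, rev_$score)))
  expect_error(kldScore(corpus[1:20], corpus), "at least")
})

test_that("property-shift reports summarize paired samples", {
  pred <- tinyPredictor()
  corpus <- tinyCorpus(300)
  a <- corpus[1:40]
  rep0 <- propertyShiftReport(a, a, pred)
  expect_equal(unname(attr(rep0, "shift")), c(0, 0), tolerance = 1e-12)
  expect_identical(rep0$n, rep(c(40L, 40L), each = 2))
  b <- corpus[41:80]
  repAB <- propertyShiftReport(a, b, pred)
  expect_identical(nrow(repAB), 4L)
  expect_true(all(c("pic50", "sas") %in% repAB$property))
})

test_that("the generation report assembles all metrics", {
  corpus <- tinyCorpus(300)
  g <- generationReport(corpus[1:150], corpus, predictor = tinyPredictor())
  expect_true(g$validity == 1)
  expect_true(g$uniqueness == 1)
  expect_equal(g$novelty, 0)
  expect_true(g$internal_diversity > 0 && g$internal_diversity < 1)
  expect_equal(g$external_diversity, 0)
  expect_true(is.na(g$fcd))
  expect_true(is.finite(g$pic50_mean_sd["mean"]))
})
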