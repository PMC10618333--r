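test_that("fixture corpora are deterministic, valid and drug-like", {
  a <- makeCorpus(200, seed = 1)
  b <- makeCorpus(200, seed = 1)
  expect_identical(a, b)
  expect_identical(length(a), 200L)
  rec <- canonicalizeSmiles(a)
  expect_true(all(rec$valid))
  expect_identical(rec$smiles_canonical, a)  # already canonical
  desc <- computeDescriptors(rec, sas = FALSE)
  expect_true(all(desc$mw >= 200 & desc$mw <= 600))
  expect_true(all(desc$logp >= -2 & desc$logp <= 6))
  expect_error(makeCorpus(1e6, seed = 1), "capacity|pass")
  expect_error(makeCorpus(0), ">= 1")
})

test_that("a third of fixture molecules carry unassigned stereocenters", {
  corpus <- tinyCorpus(300)
  graphs <- molGraphs(corpus)
  frac <- mean(vapply(graphs, function(g) {
    sc <- HitGen:::.stereoCenters(g)
    length(sc$idx) > 0 && any(!sc$assigned)
  }, logical(1)))
  expect_gte(frac, 0.3)
})

test_that("the affinity oracle counts substructures linearly", {
  # benzamide: one N, one aromatic ring, no halogen, one amide
  y <- affinityOracle("NC(=O)c1ccccc1",
                      coefficients = c(nN = 0.5, nAromRings = 0.4,
                                       nHal = 0.3, nAmide = 0.6),
                      intercept = 4, noiseSd = 0)
  expect_equal(y, 4 + 0.5 + 0.4 + 0.6)
  # halogens subtract
  yh <- affinityOracle("Clc1ccccc1", coefficients = c(nN = 0.5,
                       nAromRings = 0.4, nHal = 0.3, nAmide = 0.6),
                       intercept = 4, noiseSd = 0)
  expect_equal(yh, 4 + 0.4 - 0.3)
  # zero coefficients give the constant intercept
  y0 <- affinityOracle(c("CCO", "CCN"), coefficients = c(nN = 0,
                       nAromRings = 0, nHal = 0, nAmide = 0), intercept = 7)
  expect_equal(y0, c(7, 7))
  # seeded noise reproduces
  n1 <- affinityOracle("CCO", noiseSd = 0.5, seed = 9)
  n2 <- affinityOracle("CCO", noiseSd = 0.5, seed = 9)
  expect_identical(n1, n2)
  expect_error(affinityOracle("C("), "invalid")
})

test_that("affinity tables span the pIC50 window without duplicates", {
  tab <- tinyAffinity(300)
  expect_identical(nrow(tab), 300L)
  expect_true(all(tab$pic50 >= 4 & tab$pic50 <= 10))
  expect_false(anyDuplicated(tab$smiles) > 0)
  expect_identical(tab, makeAffinityTable(300, seed = 3, noiseSd = 0.2))
})
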