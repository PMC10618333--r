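bruteForceFront <- function(sol) {
  n <- nrow(sol)
  dominated <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    geq <- sol$pic50[j] >= sol$pic50[i] && sol$sas[j] <= sol$sas[i]
    strict <- sol$pic50[j] > sol$pic50[i] || sol$sas[j] < sol$sas[i]
    if (geq && strict) { dominated[i] <- TRUE; break }
  }
  dominated
}

test_that("the Pareto partition matches the pairwise-domination oracle", {
  one <- data.frame(smiles = "a", pic50 = 5, sas = 3)
  pf <- paretoFront(one)
  expect_identical(nrow(pf$front), 1L)
  expect_identical(nrow(pf$dominated), 0L)
  two <- data.frame(smiles = c("a", "b"), pic50 = c(6, 5), sas = c(2, 3))
  pf <- paretoFront(two)
  expect_identical(pf$front$smiles, "a")
  set.seed(12)
  for (i in 1:25) {
    n <- sample(5:120, 1)
    sol <- data.frame(smiles = paste0("m", 1:n),
                      pic50 = round(runif(n, 4, 9), sample(1:3, 1)),
                      sas = round(runif(n, 1, 8), sample(1:3, 1)))
    pf <- paretoFront(sol)
    dom <- bruteForceFront(sol)
    expect_setequal(pf$front$smiles, sol$smiles[!dom])
    expect_setequal(pf$dominated$smiles, sol$smiles[dom])
    expect_identical(nrow(pf$front) + nrow(pf$dominated), n)
  }
  expect_error(paretoFront(one[0, ]), "no solutions")
})

test_that("stereoisomer enumeration honors the 2^c bound", {
  # no centers: the molecule itself
  s0 <- enumerateStereoisomers("c1ccccc1CC")
  expect_identical(s0@nCenters, 0L)
  expect_identical(nrow(isomerTable(s0)), 1L)
  # two independent centers: exactly 4
  s2 <- enumerateStereoisomers("CC(O)C(N)CC")
  expect_identical(s2@nCenters, 2L)
  expect_identical(nrow(isomerTable(s2)), 4L)
  # all isomers share the parent's achiral skeleton
  skel <- canonicalizeSmiles(isomerTable(s2)$smiles, isomeric = FALSE)
  expect_identical(length(unique(skel$smiles_canonical)), 1L)
  # random fixtures never exceed 2^c
  corpus <- tinyCorpus(300)
  set.seed(3)
  for (s in sample(corpus, 40)) {
    st <- enumerateStereoisomers(s)
    expect_lte(nrow(isomerTable(st)), 2^st@nCenters)
    expect_gte(nrow(isomerTable(st)), 1L)
  }
  expect_error(enumerateStereoisomers("C("), "invalid")
})

test_that("stereoisomers are ranked by predicted potency, deterministically", {
  pred <- tinyPredictor()
  st <- enumerateStereoisomers("CC(O)C(N)Cc1ccccc1")
  r1 <- rankStereoisomers(st, pred)
  r2 <- rankStereoisomers(st, pred)
  expect_identical(isomerTable(r1), isomerTable(r2))
  tab <- isomerTable(r1)
  expect_identical(r1@best, 1L)
  expect_true(all(diff(tab$pic50) <= 1e-12))
  expect_true(all(tab$sas >= 1 & tab$sas <= 10))
  expect_identical(tab$rank, seq_len(nrow(tab)))
})

test_that("similarity reports match hand-derived conventions", {
  same <- similarityReport("CCO", "OCC")
  expect_equal(same$t_s, 1)
  expect_equal(same$t_mcs, 1)
  # ethane vs benzene: common C-C, atom-count Jaccard 2/(2+6-2)
  eb <- similarityReport("CC", "c1ccccc1")
  expect_equal(eb$t_mcs, 1 / 3)
  ab <- similarityReport("CCN", "CCO")
  ba <- similarityReport("CCO", "CCN")
  expect_equal(ab$t_s, ba$t_s)
  expect_equal(ab$t_mcs, ba$t_mcs)
  expect_true(ab$t_mcs <= 1 && ab$t_mcs >= 0)
})

test_that("attention atom maps conserve mass and handle one-atom molecules", {
  pred <- tinyPredictor()
  m <- attentionAtomMap(pred, "C")
  expect_identical(nrow(m), 1L)
  expect_equal(m$weight, 1)
  m2 <- attentionAtomMap(pred, "CC(=O)Nc1ccc(Cl)cc1")
  expect_equal(sum(m2$weight), 1, tolerance = 1e-6)
  expect_true(all(m2$weight >= 0))
  g <- molGraphs(canonicalizeSmiles("CC(=O)Nc1ccc(Cl)cc1")$smiles_canonical)[[1]]
  expect_identical(nrow(m2), length(g$elements))
  # a model without attention cannot provide maps
  mlp <- suppressMessages(trainPredictor(
    tinyAffinity(300)[1:80, ],
    predictorConfig("D", embeddingDim = 8, units = 8, epochs = 2,
                    patience = 2),
    seed = 1, cvFolds = 0))
  expect_error(attentionAtomMap(mlp, "CCO"), "no attention")
})
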