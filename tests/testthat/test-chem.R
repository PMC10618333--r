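test_that("canonicalization identifies molecules and rejects malformed input", {
  r <- canonicalizeSmiles(c("OCC", "CCO", "C(", "c1ccccc1"))
  expect_true(r$valid[1] && r$valid[2])
  expect_identical(r$smiles_canonical[1], r$smiles_canonical[2])
  expect_false(r$valid[3])
  expect_true(is.na(r$smiles_canonical[3]))
  expect_identical(r$smiles_raw[3], "C(")
  expect_true(r$valid[4])
  # idempotent on its own output
  again <- canonicalizeSmiles(r$smiles_canonical[r$valid])
  expect_identical(again$smiles_canonical, r$smiles_canonical[r$valid])
  expect_error(canonicalizeSmiles(character(0)))
  expect_error(canonicalizeSmiles(""))
})

test_that("the syntax gate catches errors Open Babel silently repairs", {
  bad <- c("C(", "CC)C", "C1CC", "CC(C)(C)(C)(C)C", "F=F", "C((C))O",
           "C()C", "CC=", "c1ccccc1c2", "C%12CC")
  for (s in bad) expect_false(smilesSyntaxOk(s), label = s)
  good <- c("CCO", "c1ccccc1", "C/C=C\\Cl", "CC(=O)Nc1ccc(Cl)cc1",
            "C[C@@H](N)O", "O=[N+]([O-])c1ccccc1", "CS(=O)(=O)N",
            "c1ccc2ccccc2c1", "C1CC1", "CC(C)(C)O")
  for (s in good) expect_true(smilesSyntaxOk(s), label = s)
})

test_that("training-set filter applies closed MW/logP windows", {
  rec <- data.frame(
    smiles_raw = letters[1:7], smiles_canonical = letters[1:7],
    valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    mw   = c(300, 200, 600, 199.9, 600.1, 300, 300),
    logp = c(2, -2, 6, 2, 2, 6.01, 2),
    sas  = 3, stringsAsFactors = FALSE)
  out <- filterTrainingSet(rec)
  expect_setequal(out$smiles_raw, c("a", "b", "c"))
  # benzene falls below the weight window, invalid SMILES fall out entirely
  r2 <- computeDescriptors(canonicalizeSmiles(c("c1ccccc1", "C(")), sas = FALSE)
  expect_identical(nrow(filterTrainingSet(r2)), 0L)
})

test_that("descriptors are deterministic and physically sensible", {
  rec <- computeDescriptors(canonicalizeSmiles("CCO"))
  expect_equal(rec$mw, 46.07, tolerance = 1e-3)
  expect_true(rec$sas >= 1 && rec$sas <= 10)
  rec2 <- computeDescriptors(canonicalizeSmiles("CCO"))
  expect_identical(rec$sas, rec2$sas)
})

test_that("circular fingerprints are deterministic and radius-sensitive", {
  f1 <- ecfp("CC(=O)Nc1ccc(Cl)cc1", radius = 2)
  f2 <- ecfp("CC(=O)Nc1ccc(Cl)cc1", radius = 2)
  expect_identical(f1, f2)
  expect_identical(length(f1), 2048L)
  # a pair differing only three bonds from the center distinguishes ECFP6
  a <- "CCCCCCO"; b <- "CCCCCCN"
  s4 <- tanimoto(ecfp(a, 2), ecfp(b, 2))
  s6 <- tanimoto(ecfp(a, 3), ecfp(b, 3))
  expect_false(isTRUE(all.equal(s4, s6)))
  expect_error(ecfp(""), "non-empty")
})

test_that("tanimoto follows the Jaccard definition", {
  a <- c(1, 1, 0, 0); b <- c(0, 1, 1, 0)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(c(1, 0, 0, 0), c(0, 0, 1, 0)), 0)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_error(tanimoto(a, c(1, 0)), "lengths")
  set.seed(1)
  for (i in 1:20) {
    x <- rbinom(32, 1, 0.4); y <- rbinom(32, 1, 0.4)
    v <- tanimoto(x, y)
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("SMI and CSV I/O round-trip, both line dialects parse", {
  tf <- tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene", "CCN"), tf)
  rec <- readSmilesFile(tf)
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$name[1], "ethanol")
  # CRLF dialect
  writeBin(charToRaw("CCO\r\nCCN\r\n"), tf)
  expect_identical(nrow(readSmilesFile(tf)), 2L)
  # write -> read preserves canonical SMILES
  out <- tempfile(fileext = ".smi")
  writeSmilesFile(rec, out)
  back <- readSmilesFile(out)
  expect_identical(back$smiles_canonical[1:2], rec$smiles_canonical[1:2])
  csv <- tempfile(fileext = ".csv")
  writeTable(data.frame(smiles = c("CCO", "CCN"), pic50 = c(5, 6)), csv)
  df <- utils::read.csv(csv)
  expect_identical(names(df), c("smiles", "pic50"))
  expect_error(readSmilesFile(tempfile()), "cannot read")
})
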