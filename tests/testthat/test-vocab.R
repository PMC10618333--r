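test_that("multi-character chemistry tokens are atomic", {
  v <- defaultVocabulary()
  expect_identical(tokenizeSmiles("ClCBr", v), c("Cl", "C", "Br"))
  toks <- tokenizeSmiles("C/C=C\\C", v)
  expect_true("/" %in% toks && "\\" %in% toks)
  expect_identical(tokenizeSmiles("C[C@@H](N)O", v),
                   c("C", "[C@@H]", "(", "N", ")", "O"))
  expect_identical(tokenizeSmiles("CCO", v), c("C", "C", "O"))
  # greedy longest match never splits Cl into C + l
  expect_length(tokenizeSmiles("ClCBr", v), 3L)
})

test_that("vocabulary mapping is bijective with PAD at code 0", {
  v <- defaultVocabulary()
  expect_false(anyDuplicated(vocabTokens(v)) > 0)
  expect_identical(tokenIndex(v, "<PAD>"), 0L)
  codes <- tokenIndex(v, vocabTokens(v))
  expect_identical(sort(codes), seq_len(vocabSize(v)) - 1L)
  # unknown tokens collapse onto UNK
  expect_identical(tokenIndex(v, "Zz"), tokenIndex(v, "<UNK>"))
})

test_that("pad encoding frames with GO/EOS and inverts exactly", {
  v <- defaultVocabulary()
  enc <- padEncode(c("C", "C", "O"), v, 5L)
  expect_length(enc, 7L)
  expect_identical(vocabTokens(v)[enc + 1L][1], "<GO>")
  expect_identical(vocabTokens(v)[enc + 1L][5], "<EOS>")
  expect_identical(enc[6:7], c(0L, 0L))
  expect_identical(padDecode(enc, v), c("C", "C", "O"))
  # empty payload
  enc0 <- padEncode(character(0), v, 3L)
  expect_identical(padDecode(enc0, v), character(0))
  expect_error(padEncode(rep("C", 6), v, 5L), "exceeds")
})

test_that("tokenize/detokenize round-trips over a synthetic corpus", {
  v <- defaultVocabulary()
  corpus <- tinyCorpus(300)
  for (s in corpus) {
    toks <- tokenizeSmiles(s, v)
    expect_false("<UNK>" %in% toks)
    expect_identical(detokenize(toks, v), s)
    enc <- padEncode(toks, v, 80L)
    expect_identical(padDecode(enc, v), toks)
  }
})
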