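# Shared, lazily built test artifacts. Everything is generated in code at
# test time; heavier objects are memoized for the session.

.testEnv <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.testEnv[[key]])) .testEnv[[key]] <- force(expr)
  .testEnv[[key]]
}

relErr <- function(a, b) {
  fa <- unlist(a); fb <- unlist(b)
  max(abs(fa - fb) / pmax(1e-6, abs(fa) + abs(fb)))
}

tinyCorpus <- function(n = 300) memo(paste0("corpus", n), makeCorpus(n, seed = 11))

# a quickly pretrained small generator for sampling-level tests
tinyGenerator <- function() memo("tinygen", {
  pretrainGenerator(tinyCorpus(300),
                    generatorConfig(embeddingDim = 32, units = 64,
                                    maxLen = 60, batchSize = 64,
                                    learningRate = 3e-3),
                    epochs = 25, seed = 5)
})

tinyAffinity <- function(n = 300) memo(paste0("aff", n),
                                       makeAffinityTable(n, seed = 3,
                                                         noiseSd = 0.2))

# a small trained attention predictor shared across tests
tinyPredictor <- function() memo("tinypred", {
  trainPredictor(tinyAffinity(300),
                 predictorConfig("I", embeddingDim = 32, units = 32,
                                 dropout = 0.1, epochs = 18, patience = 18,
                                 learningRate = 3e-3),
                 seed = 2, cvFolds = 0)
})
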