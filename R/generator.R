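# Recurrent SMILES language model: embedding -> two stacked LSTM layers ->
# softmax over the token vocabulary. Pre-trained by teacher forcing under the
# per-sequence-averaged categorical cross-entropy, sampled autoregressively
# with a softmax temperature.

#' SMILES language-model generator
#'
#' @slot vocab the \linkS4class{TokenVocabulary} the model emits over.
#' @slot config list of hyperparameters (see \code{\link{generatorConfig}}).
#' @slot params parameter tree (embedding, LSTM layers, output projection).
#' @slot lossTrace per-batch training loss trace.
#' @exportClass SmilesGenerator
setClass("SmilesGenerator",
  representation(vocab = "TokenVocabulary", config = "list",
                 params = "list", lossTrace = "numeric"))

setMethod("show", "SmilesGenerator", function(object) {
  cat("SmilesGenerator:", length(object@vocab@tokens), "tokens,",
      object@config$layers, "LSTM layers x", object@config$units, "units,",
      "embedding", object@config$embeddingDim, "\n")
  if (length(object@lossTrace))
    cat(" trained;", length(object@lossTrace), "batches, final loss",
        round(utils::tail(object@lossTrace, 1), 4), "\n")
})

#' Generator hyperparameters
#'
#' Two stacked LSTM layers followed by a softmax-activated dense output are
#' fixed by the architecture; the sizes and optimizer settings are free.
#'
#' @param embeddingDim token embedding width.
#' @param units hidden units per LSTM layer.
#' @param layers number of stacked LSTM layers.
#' @param maxLen maximum payload tokens per SMILES.
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param temperature default sampling temperature (> 0).
#' @return named list.
#' @export
generatorConfig <- function(embeddingDim = 64L, units = 128L, layers = 2L,
                            maxLen = 100L, learningRate = 1e-3,
                            batchSize = 128L, temperature = 1.0) {
  stopifnot(temperature > 0, units >= 1, layers >= 1)
  list(embeddingDim = as.integer(embeddingDim), units = as.integer(units),
       layers = as.integer(layers), maxLen = as.integer(maxLen),
       learningRate = learningRate, batchSize = as.integer(batchSize),
       temperature = temperature)
}

#' Accessors for a generator
#' @param object a \linkS4class{SmilesGenerator}.
#' @return \code{generatorVocab}: the vocabulary; \code{lossTrace}: numeric
#'   per-batch loss trace.
#' @export
generatorVocab <- function(object) object@vocab

#' @rdname generatorVocab
#' @export
lossTrace <- function(object) object@lossTrace

# encode a tokenized corpus into an integer matrix (1-based codes)
.encodeCorpus <- function(tokenLists, vocab, maxLen) {
  lens <- lengths(tokenLists)
  if (any(lens > maxLen))
    stop(sum(lens > maxLen), " sequences exceed maxLen = ", maxLen)
  Tmax <- max(lens) + 2L
  X <- matrix(1L, length(tokenLists), Tmax)  # 1 = PAD (0-based 0)
  for (i in seq_along(tokenLists))
    X[i, seq_len(lens[i] + 2L)] <-
      padEncode(tokenLists[[i]], vocab, lens[i]) + 1L
  X
}

#' Pre-train the SMILES generator
#'
#' Teacher-forced next-token prediction minimizing the categorical
#' cross-entropy, averaged over each sequence's length and then over the
#' batch. Minibatches are length-bucketed for efficiency; shuffling,
#' initialization and batch order are fixed by \code{seed}.
#'
#' @param corpus character vector of training SMILES (all tokenizable).
#' @param config list from \code{\link{generatorConfig}}.
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param vocab optional \linkS4class{TokenVocabulary}; defaults to one built
#'   from the corpus.
#' @param verbose print a line per epoch.
#' @return a trained \linkS4class{SmilesGenerator}.
#' @export
pretrainGenerator <- function(corpus, config = generatorConfig(), epochs = 10L,
                              seed = 1L, vocab = NULL, verbose = FALSE) {
  if (!length(corpus)) stop("empty corpus")
  if (is.null(vocab)) vocab <- vocabularyFromCorpus(corpus)
  toks <- lapply(corpus, tokenizeSmiles, vocab = vocab)
  if (any(vapply(toks, function(t) vocab@specials[["UNK"]] %in% t, logical(1))))
    stop("corpus contains tokens outside the vocabulary")
  .withSeed(seed, {
    params <- .lstmInitParams(vocabSize(vocab), config$embeddingDim,
                              config$units, config$layers)
    X <- .encodeCorpus(toks, vocab, config$maxLen)
    lens <- lengths(toks) + 1L  # payload + EOS = number of predicted tokens
    ord <- order(lens)          # length bucketing
    nb <- ceiling(length(ord) / config$batchSize)
    batches <- split(ord, rep(seq_len(nb), each = config$batchSize,
                              length.out = length(ord)))
    adam <- .adamInit(params)
    trace <- numeric(0)
    for (ep in seq_len(epochs)) {
      for (bi in sample(nb)) {
        idx <- batches[[bi]]
        Tb <- max(lens[idx]) + 1L
        Xb <- X[idx, seq_len(Tb), drop = FALSE]
        res <- .generatorStep(params, Xb, lens[idx])
        grads <- .clipByNorm(res$grads, 5)
        params <- .adamStep(params, grads, adam, config$learningRate)
        trace <- c(trace, res$loss)
      }
      if (verbose)
        message(sprintf("epoch %d  loss %.4f", ep,
                        mean(utils::tail(trace, nb))))
    }
    new("SmilesGenerator", vocab = vocab, config = config, params = params,
        lossTrace = trace)
  })
}

# teacher-forced loss/grad on an encoded batch; weights 1/T_b per sequence
.generatorStep <- function(params, Xb, lens) {
  B <- nrow(Xb)
  T_ <- ncol(Xb) - 1L
  Xin <- Xb[, seq_len(T_), drop = FALSE]
  Tgt <- Xb[, 1L + seq_len(T_), drop = FALSE]
  fwd <- .lstmForward(params, Xin)
  loss <- 0
  dlog <- vector("list", T_)
  for (t in seq_len(T_)) {
    w <- ifelse(t <= lens, 1 / (lens * B), 0)
    ce <- .softmaxCEGrad(fwd$probs[[t]], Tgt[, t], w)
    loss <- loss + ce$loss
    dlog[[t]] <- ce$dlogits
  }
  grads <- .lstmBackward(params, Xin, fwd, dlog)
  list(loss = loss, grads = grads)
}

#' Sample SMILES strings from the generator
#'
#' Autoregressive decoding: at each step the logits are divided by
#' \code{temperature} before the softmax; generation stops at EOS (or PAD) or
#' after \code{maxLen} tokens. As temperature approaches 0 the sampling
#' collapses to greedy argmax decoding; temperature 1 samples the model
#' distribution unchanged.
#'
#' @param generator a trained \linkS4class{SmilesGenerator}.
#' @param n number of strings (>= 1).
#' @param temperature positive softmax temperature.
#' @param seed integer seed.
#' @param maxLen cap on emitted tokens (defaults to the model's).
#' @return character vector of \code{n} raw SMILES (validity not guaranteed).
#' @export
sampleSmiles <- function(generator, n, temperature = 0.8, seed = 1L,
                         maxLen = generator@config$maxLen) {
  if (n <= 0) stop("n must be positive")
  if (temperature <= 0) stop("temperature must be > 0")
  vocab <- generator@vocab
  sp <- vocab@specials
  goId <- tokenIndex(vocab, sp[["GO"]]) + 1L
  eosId <- tokenIndex(vocab, sp[["EOS"]]) + 1L
  padId <- tokenIndex(vocab, sp[["PAD"]]) + 1L
  .withSeed(seed, {
    out <- character(0)
    remaining <- n
    while (remaining > 0) {
      B <- min(remaining, 256L)
      state <- .lstmStateInit(generator@params, B)
      tokens <- rep(goId, B)
      done <- rep(FALSE, B)
      seqs <- matrix(padId, B, maxLen)
      for (t in seq_len(maxLen)) {
        st <- .lstmStep(generator@params, tokens, state)
        state <- st$state
        probs <- .softmaxRows(st$logits / temperature)
        nxt <- vapply(seq_len(B), function(b) {
          if (done[b]) return(padId)
          sample.int(ncol(probs), 1L, prob = probs[b, ])
        }, integer(1))
        newdone <- nxt %in% c(eosId, padId)
        seqs[cbind(seq_len(B), rep(t, B))] <- ifelse(done | newdone, padId, nxt)
        done <- done | newdone
        tokens <- ifelse(done, padId, nxt)
        if (all(done)) break
      }
      out <- c(out, apply(seqs, 1L, function(row) {
        detokenize(vocab@tokens[row[row != padId]], vocab)
      }))
      remaining <- remaining - B
    }
    out
  })
}

#' Per-step log-probabilities of a sequence under the generator
#'
#' Teacher-forces the encoded sequence (GO-prefixed) through the model and
#' returns \eqn{\ln \pi(A_t | S_t)} for each emitted token including the
#' terminating EOS. The sum is the log-probability of the whole sequence.
#'
#' @param generator a trained \linkS4class{SmilesGenerator}.
#' @param smiles single SMILES string, every token inside the vocabulary.
#' @return numeric vector of per-step log-probabilities (each <= 0).
#' @export
sequenceLogProbs <- function(generator, smiles) {
  vocab <- generator@vocab
  toks <- tokenizeSmiles(smiles, vocab)
  if (vocab@specials[["UNK"]] %in% toks)
    stop("sequence contains tokens outside the vocabulary")
  codes <- padEncode(toks, vocab, length(toks)) + 1L
  T_ <- length(codes) - 1L
  Xin <- matrix(codes[seq_len(T_)], 1L)
  fwd <- .lstmForward(generator@params, Xin)
  vapply(seq_len(T_), function(t) log(fwd$probs[[t]][1L, codes[t + 1L]]),
         numeric(1))
}
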