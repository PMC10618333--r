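# pIC50 regression from SMILES or fingerprints. Ten legal configurations
# (A-J) pair a descriptor (ECFP4/ECFP6/path fingerprint/raw SMILES) with an
# architecture (multi-layer feed-forward, GRU, bidirectional GRU, stacked
# bidirectional, separated bidirectional) and optionally additive attention
# pooling. Sequences are processed in exact-length groups, so no padding or
# masking ever enters the recurrence and batch composition cannot change a
# prediction.

.PREDICTOR_TABLE <- list(
  A = list(descriptor = "ECFP4",  architecture = "mlp",       attention = FALSE),
  B = list(descriptor = "ECFP6",  architecture = "mlp",       attention = FALSE),
  C = list(descriptor = "path",   architecture = "mlp",       attention = FALSE),
  D = list(descriptor = "SMILES", architecture = "rnn",       attention = FALSE),
  E = list(descriptor = "SMILES", architecture = "rnn",       attention = TRUE),
  F = list(descriptor = "SMILES", architecture = "birnn",     attention = FALSE),
  G = list(descriptor = "SMILES", architecture = "birnn",     attention = TRUE),
  H = list(descriptor = "SMILES", architecture = "birnn_rnn", attention = FALSE),
  I = list(descriptor = "SMILES", architecture = "birnn_rnn", attention = TRUE),
  J = list(descriptor = "SMILES", architecture = "sep_birnn", attention = TRUE))

#' Predictor configuration (models A-J)
#'
#' The configuration family pairs descriptors with architectures; attention is
#' only legal with the sequence descriptor. Model \code{"I"} (bidirectional
#' recurrent + recurrent + attention pooling) is the default and the
#' best-performing member.
#'
#' @param model one of \code{"A"}..\code{"J"}.
#' @param embeddingDim token embedding width (sequence models).
#' @param units recurrent units per direction.
#' @param dropout dropout rate on the pooled representation.
#' @param denseUnits hidden sizes of the feed-forward models.
#' @param fpBits fingerprint length for descriptor models.
#' @param learningRate,batchSize,epochs,patience training settings; training
#'   runs at most \code{epochs} epochs with early stopping after
#'   \code{patience} epochs without validation improvement, restoring the best
#'   checkpoint.
#' @return named list.
#' @export
predictorConfig <- function(model = "I", embeddingDim = 256L, units = 128L,
                            dropout = 0.3, denseUnits = c(256L, 64L),
                            fpBits = 1024L, learningRate = 1e-3,
                            batchSize = 32L, epochs = 50L, patience = 15L) {
  model <- match.arg(model, names(.PREDICTOR_TABLE))
  row <- .PREDICTOR_TABLE[[model]]
  if (row$attention && row$descriptor != "SMILES")
    stop("attention requires the sequence descriptor")  # unreachable by table
  c(list(model = model), row,
    list(embeddingDim = as.integer(embeddingDim), units = as.integer(units),
         dropout = dropout, denseUnits = as.integer(denseUnits),
         fpBits = as.integer(fpBits), learningRate = learningRate,
         batchSize = as.integer(batchSize), epochs = as.integer(epochs),
         patience = as.integer(patience)))
}

#' pIC50 predictor
#'
#' @slot config list from \code{\link{predictorConfig}}.
#' @slot vocab token vocabulary (sequence models).
#' @slot params trained parameter tree.
#' @slot scaler label scaler (median/IQR) in pIC50 units.
#' @slot metrics cross-validation and hold-out metrics.
#' @exportClass Pic50Predictor
setClass("Pic50Predictor",
  representation(config = "list", vocab = "TokenVocabulary", params = "list",
                 scaler = "list", metrics = "list"))

setMethod("show", "Pic50Predictor", function(object) {
  cat("Pic50Predictor configuration", object@config$model,
      sprintf("(%s / %s%s)\n", object@config$descriptor,
              object@config$architecture,
              if (object@config$attention) " + attention" else ""))
  if (!is.null(object@metrics$holdout))
    cat(sprintf(" hold-out: MSE %.3f  Q2 %.3f  CCC %.3f\n",
                object@metrics$holdout$mse, object@metrics$holdout$q2,
                object@metrics$holdout$ccc))
})

#' Cross-validation and hold-out metrics of a trained predictor
#' @param object a \linkS4class{Pic50Predictor}.
#' @return list with \code{folds} (data.frame) and \code{holdout}.
#' @export
predictorMetrics <- function(object) object@metrics

# ---- label standardization --------------------------------------------------

#' Robust label standardization by median and interquartile range
#'
#' \code{standardizeLabels} returns the scaler (median, IQR with
#' linear-interpolation quartiles) and the transformed values
#' \eqn{z = (y - median)/IQR}; \code{invertLabels} is its exact inverse.
#'
#' @param y numeric labels (>= 4 values, non-constant).
#' @param scaler list with \code{median} and \code{iqr}.
#' @param z standardized values.
#' @return \code{standardizeLabels}: list with \code{scaler} and \code{z};
#'   \code{invertLabels}: numeric vector in label units.
#' @export
standardizeLabels <- function(y) {
  if (length(y) < 4) stop("need at least 4 labels")
  q <- stats::quantile(y, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  if (iqr <= 0) stop("degenerate label scale: IQR is zero")
  scaler <- list(median = q[2], iqr = iqr)
  list(scaler = scaler, z = (y - q[2]) / iqr)
}

#' @rdname standardizeLabels
#' @export
invertLabels <- function(scaler, z) z * scaler$iqr + scaler$median

# ---- regression metrics -----------------------------------------------------

#' Regression metrics: MSE, RMSE, Q2 and concordance correlation
#'
#' \eqn{Q^2 = 1 - SS_{res}/SS_{tot}} and Lin's concordance
#' \eqn{CCC = 2\,\mathrm{cov}(y,\hat y) / (\sigma_y^2 + \sigma_{\hat y}^2 +
#' (\mu_y - \mu_{\hat y})^2)} with population moments.
#'
#' @param y observed values.
#' @param yhat predicted values (same length, >= 2).
#' @return list with \code{mse}, \code{rmse}, \code{q2}, \code{ccc}.
#' @export
regressionMetrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 values")
  n <- length(y)
  mse <- mean((y - yhat)^2)
  sstot <- sum((y - mean(y))^2)
  q2 <- if (sstot > 0) 1 - sum((y - yhat)^2) / sstot else NA_real_
  vy <- mean((y - mean(y))^2)
  vh <- mean((yhat - mean(yhat))^2)
  cv <- mean((y - mean(y)) * (yhat - mean(yhat)))
  den <- vy + vh + (mean(y) - mean(yhat))^2
  ccc <- if (den > 0) 2 * cv / den else 1
  list(mse = mse, rmse = sqrt(mse), q2 = q2, ccc = ccc)
}

#' Additive attention pooling over hidden states
#'
#' Scores each hidden state against a learned output query through a dense
#' alignment layer, applies tanh then a softmax over positions, and pools the
#' states by the resulting weights: \eqn{C_m = \sum_i \alpha_i h_i}.
#'
#' @param hidden T x D matrix of hidden-state vectors (T >= 1).
#' @param query length-D alignment query (defaults to ones).
#' @param bias alignment bias.
#' @return list with \code{alphas} (length T, non-negative, summing to 1) and
#'   \code{context} (length D).
#' @export
attentionPool <- function(hidden, query = rep(1, ncol(hidden)), bias = 0) {
  if (!is.matrix(hidden) || nrow(hidden) < 1) stop("need at least one hidden state")
  p <- list(q = query, b = bias)
  hs <- lapply(seq_len(nrow(hidden)), function(t) hidden[t, , drop = FALSE])
  at <- .attnForward(p, hs)
  list(alphas = as.vector(at$alpha), context = as.vector(at$context))
}

# ---- parameter initialization ----------------------------------------------

.predInitParams <- function(cfg, vocabSize) {
  U <- cfg$units
  if (cfg$architecture == "mlp") {
    d <- cfg$denseUnits
    return(list(W1 = .glorot(cfg$fpBits, d[1]), b1 = rep(0, d[1]),
                W2 = .glorot(d[1], d[2]), b2 = rep(0, d[2]),
                W3 = .glorot(d[2], 1L), b3 = 0))
  }
  p <- list(emb = .glorot(vocabSize, cfg$embeddingDim))
  p$gru1f <- .gruInitParams(cfg$embeddingDim, U)
  if (cfg$architecture %in% c("birnn", "birnn_rnn", "sep_birnn"))
    p$gru1b <- .gruInitParams(cfg$embeddingDim, U)
  if (cfg$architecture == "birnn_rnn")
    p$gru2 <- .gruInitParams(2L * U, U)
  poolDim <- switch(cfg$architecture,
                    rnn = U, birnn = 2L * U, birnn_rnn = U, sep_birnn = 2L * U)
  if (cfg$attention) {
    if (cfg$architecture == "sep_birnn") {
      p$attnF <- .attnInitParams(U)
      p$attnB <- .attnInitParams(U)
    } else p$attn <- .attnInitParams(poolDim)
  }
  p$Wd <- .glorot(poolDim, 1L)
  p$bd <- 0
  p
}

# ---- forward / backward -----------------------------------------------------

# X: B x T matrix of 1-based codes, all rows the same true length (no pads)
.predForwardSeq <- function(params, cfg, X, dropMask = NULL) {
  B <- nrow(X); T_ <- ncol(X)
  xs <- lapply(seq_len(T_), function(t) params$emb[X[, t], , drop = FALSE])
  arch <- cfg$architecture
  cache <- list(xs = xs)
  if (arch == "rnn") {
    f1 <- .gruForward(params$gru1f, xs)
    hs <- f1$hs
    cache$f1 <- f1
  } else {
    xsrev <- xs[rev(seq_len(T_))]
    f1 <- .gruForward(params$gru1f, xs)
    b1 <- .gruForward(params$gru1b, xsrev)
    cache$f1 <- f1; cache$b1 <- b1
    if (arch == "sep_birnn") {
      hs <- NULL
    } else {
      hs <- lapply(seq_len(T_), function(t)
        cbind(f1$hs[[t]], b1$hs[[T_ + 1L - t]]))
      if (arch == "birnn_rnn") {
        f2 <- .gruForward(params$gru2, hs)
        cache$hcat <- hs
        hs <- f2$hs
        cache$f2 <- f2
      }
    }
  }
  if (arch == "sep_birnn") {
    atF <- .attnForward(params$attnF, cache$f1$hs)
    atB <- .attnForward(params$attnB, cache$b1$hs)
    ctx <- cbind(atF$context, atB$context)
    cache$atF <- atF; cache$atB <- atB
    alpha <- (atF$alpha + atB$alpha[, rev(seq_len(T_)), drop = FALSE]) / 2
  } else if (cfg$attention) {
    at <- .attnForward(params$attn, hs)
    ctx <- at$context
    alpha <- at$alpha
    cache$at <- at; cache$hs <- hs
  } else {
    ctx <- hs[[T_]]
    alpha <- NULL
    cache$hs <- hs
  }
  cache$ctx <- ctx
  if (is.null(dropMask)) dropMask <- matrix(1, B, ncol(ctx))
  ctxd <- ctx * dropMask
  cache$ctxd <- ctxd; cache$dropMask <- dropMask
  pred <- as.vector(ctxd %*% params$Wd) + params$bd
  list(pred = pred, alpha = alpha, cache = cache)
}

.predBackwardSeq <- function(params, cfg, X, fwd, dpred) {
  B <- nrow(X); T_ <- ncol(X)
  arch <- cfg$architecture
  cache <- fwd$cache
  g <- .treeZero(params)
  g$Wd <- crossprod(cache$ctxd, dpred)
  g$bd <- sum(dpred)
  dctx <- outer(dpred, params$Wd[, 1]) * cache$dropMask
  U <- cfg$units
  zero <- function() matrix(0, B, U)
  if (arch == "sep_birnn") {
    abF <- .attnBackward(params$attnF, cache$atF, dctx[, 1:U, drop = FALSE])
    abB <- .attnBackward(params$attnB, cache$atB,
                         dctx[, (U + 1):(2 * U), drop = FALSE])
    g$attnF <- abF$grads; g$attnB <- abB$grads
    gbF <- .gruBackward(params$gru1f, cache$f1, abF$dhs)
    gbB <- .gruBackward(params$gru1b, cache$b1, abB$dhs)
    g$gru1f <- gbF$grads; g$gru1b <- gbB$grads
    dxs <- lapply(seq_len(T_), function(t)
      gbF$dxs[[t]] + gbB$dxs[[T_ + 1L - t]])
  } else {
    if (cfg$attention) {
      ab <- .attnBackward(params$attn, cache$at, dctx)
      g$attn <- ab$grads
      dhs <- ab$dhs
    } else {
      dhs <- rep(list(matrix(0, B, ncol(cache$ctx))), T_)
      dhs[[T_]] <- dctx
    }
    if (arch == "rnn") {
      gb <- .gruBackward(params$gru1f, cache$f1, dhs)
      g$gru1f <- gb$grads
      dxs <- gb$dxs
    } else {
      if (arch == "birnn_rnn") {
        gb2 <- .gruBackward(params$gru2, cache$f2, dhs)
        g$gru2 <- gb2$grads
        dhcat <- gb2$dxs
      } else dhcat <- dhs
      dhf <- lapply(dhcat, function(m) m[, 1:U, drop = FALSE])
      dhb <- vector("list", T_)
      for (t in seq_len(T_))
        dhb[[T_ + 1L - t]] <- dhcat[[t]][, (U + 1):(2 * U), drop = FALSE]
      gbF <- .gruBackward(params$gru1f, cache$f1, dhf)
      gbB <- .gruBackward(params$gru1b, cache$b1, dhb)
      g$gru1f <- gbF$grads; g$gru1b <- gbB$grads
      dxs <- lapply(seq_len(T_), function(t)
        gbF$dxs[[t]] + gbB$dxs[[T_ + 1L - t]])
    }
  }
  toks <- as.vector(X)
  rs <- rowsum(do.call(rbind, dxs), group = toks)
  ids <- as.integer(rownames(rs))
  g$emb[ids, ] <- g$emb[ids, , drop = FALSE] + rs
  g
}

.predForwardMlp <- function(params, X, dropMask = NULL) {
  h1 <- pmax(sweep(X %*% params$W1, 2L, params$b1, `+`), 0)
  h2 <- pmax(sweep(h1 %*% params$W2, 2L, params$b2, `+`), 0)
  if (is.null(dropMask)) dropMask <- matrix(1, nrow(X), ncol(h2))
  h2d <- h2 * dropMask
  pred <- as.vector(h2d %*% params$W3) + params$b3
  list(pred = pred, alpha = NULL,
       cache = list(h1 = h1, h2 = h2, h2d = h2d, dropMask = dropMask, X = X))
}

.predBackwardMlp <- function(params, fwd, dpred) {
  c_ <- fwd$cache
  g <- .treeZero(params)
  g$W3 <- crossprod(c_$h2d, dpred)
  g$b3 <- sum(dpred)
  dh2 <- outer(dpred, params$W3[, 1]) * c_$dropMask * (c_$h2 > 0)
  g$W2 <- crossprod(c_$h1, dh2)
  g$b2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(params$W2)) * (c_$h1 > 0)
  g$W1 <- crossprod(c_$X, dh1)
  g$b1 <- colSums(dh1)
  g
}

# ---- descriptor / encoding helpers -----------------------------------------

.fpForSmiles <- function(smiles, descriptor, nbits) {
  key <- paste0("fp_", descriptor, "_", nbits)
  if (is.null(.hitgenCache[[key]])) .hitgenCache[[key]] <- new.env(parent = emptyenv())
  envc <- .hitgenCache[[key]]
  t(vapply(smiles, function(s) {
    hit <- envc[[s]]
    if (!is.null(hit)) return(hit)
    fp <- switch(descriptor,
      ECFP4 = as.numeric(ecfp(s, radius = 2, nbits = nbits)),
      ECFP6 = as.numeric(ecfp(s, radius = 3, nbits = nbits)),
      path = {
        mol <- ChemmineOB::forEachMol("SMILES", s, identity)
        bits <- ChemmineOB::fingerprint_OB(mol, "FP2")
        as.numeric(colSums(matrix(bits, ncol = nbits, byrow = TRUE)) > 0)
      })
    envc[[s]] <- fp
    fp
  }, numeric(nbits), USE.NAMES = FALSE))
}

# encode SMILES to 1-based code vectors (payload tokens only, no framing)
.encodeForPredictor <- function(smiles, vocab) {
  lapply(smiles, function(s) tokenIndex(vocab, tokenizeSmiles(s, vocab)) + 1L)
}

# group sequence indices by exact length, chunked to the batch size
.lengthBatches <- function(codes, batchSize) {
  lens <- lengths(codes)
  groups <- split(seq_along(codes), lens)
  unlist(lapply(groups, function(idx) {
    nb <- ceiling(length(idx) / batchSize)
    split(idx, rep(seq_len(nb), each = batchSize, length.out = length(idx)))
  }), recursive = FALSE, use.names = FALSE)
}

# ---- training ---------------------------------------------------------------

.predEvaluate <- function(params, cfg, codes, fps, z, idx, batchSize) {
  preds <- numeric(length(idx))
  names(preds) <- as.character(idx)
  if (cfg$architecture == "mlp") {
    fwd <- .predForwardMlp(params, fps[idx, , drop = FALSE])
    preds[] <- fwd$pred
  } else {
    for (batch in .lengthBatches(codes[idx], batchSize)) {
      gi <- idx[batch]
      X <- do.call(rbind, codes[gi])
      fwd <- .predForwardSeq(params, cfg, X)
      preds[as.character(gi)] <- fwd$pred
    }
  }
  mean((preds - z[idx])^2)
}

.predTrainLoop <- function(params, cfg, codes, fps, z, trainIdx, valIdx,
                           epochs, patience, lr, verbose = FALSE) {
  adam <- .adamInit(params)
  best <- params
  bestVal <- Inf
  wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    perm <- sample(length(trainIdx))
    shuffled <- trainIdx[perm]
    batches <- if (cfg$architecture == "mlp") {
      nb <- ceiling(length(shuffled) / cfg$batchSize)
      split(seq_along(shuffled), rep(seq_len(nb), each = cfg$batchSize,
                                     length.out = length(shuffled)))
    } else .lengthBatches(codes[shuffled], cfg$batchSize)
    for (batch in batches) {
      gi <- shuffled[batch]
      if (cfg$architecture == "mlp") {
        Xb <- fps[gi, , drop = FALSE]
        mask <- matrix(stats::rbinom(length(gi) * cfg$denseUnits[2], 1L,
                                     1 - cfg$dropout) / (1 - cfg$dropout),
                       length(gi), cfg$denseUnits[2])
        fwd <- .predForwardMlp(params, Xb, mask)
        dpred <- 2 * (fwd$pred - z[gi]) / length(gi)
        grads <- .predBackwardMlp(params, fwd, dpred)
      } else {
        X <- do.call(rbind, codes[gi])
        poolDim <- switch(cfg$architecture, rnn = cfg$units,
                          birnn = 2L * cfg$units, birnn_rnn = cfg$units,
                          sep_birnn = 2L * cfg$units)
        mask <- matrix(stats::rbinom(length(gi) * poolDim, 1L,
                                     1 - cfg$dropout) / (1 - cfg$dropout),
                       length(gi), poolDim)
        fwd <- .predForwardSeq(params, cfg, X, mask)
        dpred <- 2 * (fwd$pred - z[gi]) / length(gi)
        grads <- .predBackwardSeq(params, cfg, X, fwd, dpred)
      }
      grads <- .clipByNorm(grads, 5)
      params <- .adamStep(params, grads, adam, lr)
    }
    val <- .predEvaluate(params, cfg, codes, fps, z, valIdx, cfg$batchSize)
    history <- c(history, val)
    if (verbose) message(sprintf("  epoch %d val MSE %.4f", ep, val))
    if (val < bestVal - 1e-6) {
      bestVal <- val
      best <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(params = best, valMse = bestVal, history = history)
}

#' Train a pIC50 predictor
#'
#' Canonicalizes the dataset (invalid SMILES are dropped with a message,
#' duplicate canonical structures collapsed), carves out a hold-out fraction,
#' then runs cross-validation: each fold is an independent 85/15
#' train/validation split of the remaining pool. Every run uses Adam, at most
#' \code{config$epochs} epochs, early stopping with \code{config$patience}
#' and best-checkpoint restoration. The final model is trained on the pool
#' and assessed on the hold-out set.
#'
#' @param data data.frame with columns \code{smiles} and \code{pic50}
#'   (>= 50 rows).
#' @param config list from \code{\link{predictorConfig}}.
#' @param seed integer seed fixing splits, initialization and shuffling.
#' @param cvFolds number of cross-validation folds (0 skips CV).
#' @param holdoutFraction fraction reserved before CV.
#' @param verbose print progress.
#' @return a trained \linkS4class{Pic50Predictor}; per-fold and hold-out
#'   metrics in \code{predictorMetrics()}.
#' @export
trainPredictor <- function(data, config = predictorConfig(), seed = 1L,
                           cvFolds = 5L, holdoutFraction = 0.1,
                           verbose = FALSE) {
  stopifnot(all(c("smiles", "pic50") %in% names(data)))
  rec <- canonicalizeSmiles(as.character(data$smiles))
  bad <- sum(!rec$valid)
  if (bad) message(bad, " unparseable SMILES dropped")
  keep <- rec$valid & !duplicated(rec$smiles_canonical)
  smiles <- rec$smiles_canonical[keep]
  y <- as.numeric(data$pic50)[keep]
  if (length(smiles) < 50) stop("need at least 50 parseable molecules")
  vocab <- vocabularyFromCorpus(smiles)
  .withSeed(seed, {
    n <- length(smiles)
    hold <- sample(n, max(1L, round(holdoutFraction * n)))
    pool <- setdiff(seq_len(n), hold)
    std <- standardizeLabels(y[pool])
    z <- (y - std$scaler$median) / std$scaler$iqr
    codes <- fps <- NULL
    if (config$architecture == "mlp") {
      fps <- .fpForSmiles(smiles, config$descriptor, config$fpBits)
    } else {
      codes <- .encodeForPredictor(smiles, vocab)
    }
    foldMetrics <- NULL
    if (cvFolds > 0) {
      rows <- vector("list", cvFolds)
      for (k in seq_len(cvFolds)) {
        vi <- sample(pool, round(0.15 * length(pool)))
        ti <- setdiff(pool, vi)
        params <- .predInitParams(config, vocabSize(vocab))
        fit <- .predTrainLoop(params, config, codes, fps, z, ti, vi,
                              config$epochs, config$patience,
                              config$learningRate, verbose)
        preds <- .predPredictZ(fit$params, config, codes, fps, vi,
                               config$batchSize)
        m <- regressionMetrics(y[vi], invertLabels(std$scaler, preds))
        rows[[k]] <- data.frame(fold = k, mse = m$mse, rmse = m$rmse,
                                q2 = m$q2, ccc = m$ccc)
        if (verbose) message(sprintf("fold %d: MSE %.3f Q2 %.3f", k, m$mse, m$q2))
      }
      foldMetrics <- do.call(rbind, rows)
    }
    vi <- sample(pool, round(0.15 * length(pool)))
    ti <- setdiff(pool, vi)
    params <- .predInitParams(config, vocabSize(vocab))
    fit <- .predTrainLoop(params, config, codes, fps, z, ti, vi,
                          config$epochs, config$patience,
                          config$learningRate, verbose)
    predsH <- .predPredictZ(fit$params, config, codes, fps, hold,
                            config$batchSize)
    holdMetrics <- regressionMetrics(y[hold], invertLabels(std$scaler, predsH))
    new("Pic50Predictor", config = config, vocab = vocab, params = fit$params,
        scaler = std$scaler,
        metrics = list(folds = foldMetrics, holdout = holdMetrics,
                       nDropped = bad))
  })
}

.predPredictZ <- function(params, cfg, codes, fps, idx, batchSize) {
  preds <- numeric(length(idx))
  names(preds) <- as.character(idx)
  if (cfg$architecture == "mlp") {
    fwd <- .predForwardMlp(params, fps[idx, , drop = FALSE])
    preds[] <- fwd$pred
  } else {
    for (batch in .lengthBatches(codes[idx], batchSize)) {
      gi <- idx[batch]
      X <- do.call(rbind, codes[gi])
      fwd <- .predForwardSeq(params, cfg, X)
      preds[as.character(gi)] <- fwd$pred
    }
  }
  unname(preds)
}

#' Fine-tune a trained predictor on a focused subset
#'
#' Continues training on the subset only, at a reduced learning rate
#' (\code{lrFactor} times the base rate). With \code{epochs = 0} the model is
#' returned unchanged.
#'
#' @param predictor a trained \linkS4class{Pic50Predictor}.
#' @param data non-empty data.frame with \code{smiles}, \code{pic50}.
#' @param epochs fine-tuning epochs.
#' @param lrFactor learning-rate reduction factor.
#' @param seed integer seed.
#' @return the fine-tuned \linkS4class{Pic50Predictor}.
#' @export
fineTune <- function(predictor, data, epochs = 10L, lrFactor = 0.1,
                     seed = 1L) {
  if (!nrow(data)) stop("empty fine-tuning subset")
  if (epochs == 0) return(predictor)
  cfg <- predictor@config
  rec <- canonicalizeSmiles(as.character(data$smiles))
  keep <- rec$valid
  smiles <- rec$smiles_canonical[keep]
  y <- as.numeric(data$pic50)[keep]
  if (!length(smiles)) stop("no parseable molecules in the subset")
  z <- (y - predictor@scaler$median) / predictor@scaler$iqr
  codes <- fps <- NULL
  if (cfg$architecture == "mlp") {
    fps <- .fpForSmiles(smiles, cfg$descriptor, cfg$fpBits)
  } else codes <- .encodeForPredictor(smiles, predictor@vocab)
  .withSeed(seed, {
    fit <- .predTrainLoop(predictor@params, cfg, codes, fps, z,
                          seq_along(smiles), seq_along(smiles),
                          epochs, epochs + 1L, cfg$learningRate * lrFactor)
    predictor@params <- fit$params
    predictor
  })
}

#' Predict pIC50 for SMILES
#'
#' Canonicalizes each input (so any spelling of the same molecule predicts
#' identically), runs the model and de-standardizes back to pIC50 units.
#' Invalid SMILES are flagged and get NA.
#'
#' @param predictor a trained \linkS4class{Pic50Predictor}.
#' @param smiles character vector.
#' @return data.frame with \code{smiles}, \code{valid}, \code{pic50}.
#' @export
predictPic50 <- function(predictor, smiles) {
  rec <- canonicalizeSmiles(as.character(smiles))
  out <- data.frame(smiles = smiles, valid = rec$valid, pic50 = NA_real_,
                    stringsAsFactors = FALSE)
  vidx <- which(rec$valid)
  if (!length(vidx)) return(out)
  cfg <- predictor@config
  can <- rec$smiles_canonical[vidx]
  if (cfg$architecture == "mlp") {
    fps <- .fpForSmiles(can, cfg$descriptor, cfg$fpBits)
    preds <- .predPredictZ(predictor@params, cfg, NULL, fps,
                           seq_along(can), cfg$batchSize)
  } else {
    codes <- .encodeForPredictor(can, predictor@vocab)
    preds <- .predPredictZ(predictor@params, cfg, codes, NULL,
                           seq_along(can), cfg$batchSize)
  }
  out$pic50[vidx] <- invertLabels(predictor@scaler, preds)
  out
}

#' Per-token attention weights for one molecule
#'
#' Requires an attention-bearing configuration. The weights are non-negative,
#' sum to 1 and align one-to-one with the SMILES tokens of the canonical form.
#'
#' @param predictor a trained attention \linkS4class{Pic50Predictor}.
#' @param smiles single valid SMILES.
#' @return list with \code{tokens} and \code{alphas}.
#' @export
attentionWeights <- function(predictor, smiles) {
  cfg <- predictor@config
  if (!isTRUE(cfg$attention))
    stop("configuration ", cfg$model, " has no attention mechanism")
  rec <- canonicalizeSmiles(smiles)
  if (!rec$valid[1]) stop("invalid SMILES: ", smiles)
  can <- rec$smiles_canonical[1]
  toks <- tokenizeSmiles(can, predictor@vocab)
  X <- matrix(tokenIndex(predictor@vocab, toks) + 1L, 1L)
  fwd <- .predForwardSeq(predictor@params, cfg, X)
  list(tokens = toks, alphas = as.vector(fwd$alpha),
       smiles = can,
       pic50 = invertLabels(predictor@scaler, fwd$pred))
}
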