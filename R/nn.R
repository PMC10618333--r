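# Minimal neural-network kernel used by the generator and the predictor.
# Dense linear algebra only (BLAS via %*%); parameters and gradients live in
# nested named lists with identical shape, and every backward pass here is
# checked against central finite differences in the test suite.

.sigm <- function(x) 1 / (1 + exp(-x))

.softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# ---- parameter-tree utilities ----------------------------------------------

.treeMap <- function(f, a) {
  if (is.list(a)) lapply(a, .treeMap, f = f) else f(a)
}

.treeMap2 <- function(f, a, b) {
  if (is.list(a)) mapply(.treeMap2, a, b, MoreArgs = list(f = f),
                         SIMPLIFY = FALSE)
  else f(a, b)
}

.treeZero <- function(a) .treeMap(function(x) x * 0, a)

.treeSumSq <- function(a) {
  if (is.list(a)) sum(vapply(a, .treeSumSq, numeric(1))) else sum(a^2)
}

.clipByNorm <- function(grads, maxNorm) {
  nrm <- sqrt(.treeSumSq(grads))
  if (is.finite(nrm) && nrm > maxNorm)
    grads <- .treeMap(function(x) x * (maxNorm / nrm), grads)
  grads
}

.adamInit <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- .treeZero(params)
  st$v <- .treeZero(params)
  st$t <- 0L
  st
}

.adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- .treeMap2(function(m, g) beta1 * m + (1 - beta1) * g, st$m, grads)
  st$v <- .treeMap2(function(v, g) beta2 * v + (1 - beta2) * g^2, st$v, grads)
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  upd <- .treeMap2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   st$m, st$v)
  .treeMap2(`-`, params, upd)
}

# ---- losses -----------------------------------------------------------------

# weighted categorical cross-entropy on softmax outputs;
# dlogits = (p - onehot(target)) * w  is exact for logits pre-softmax
.softmaxCEGrad <- function(probs, targets, weights) {
  B <- nrow(probs)
  ptarget <- probs[cbind(seq_len(B), targets)]
  loss <- -sum(weights * log(pmax(ptarget, 1e-12)))
  dlogits <- probs * weights
  dlogits[cbind(seq_len(B), targets)] <-
    dlogits[cbind(seq_len(B), targets)] - weights
  list(loss = loss, dlogits = dlogits)
}

# ---- LSTM stack (generator backbone) ---------------------------------------

.lstmInitParams <- function(vocabSize, embeddingDim, units, layers = 2L) {
  lay <- vector("list", layers)
  for (l in seq_len(layers)) {
    nin <- if (l == 1L) embeddingDim else units
    lay[[l]] <- list(W = .glorot(nin, 4L * units),
                     U = .glorot(units, 4L * units),
                     b = rep(0, 4L * units))
    # forget-gate bias at 1 for stable early training
    lay[[l]]$b[(units + 1L):(2L * units)] <- 1
  }
  list(emb = .glorot(vocabSize, embeddingDim),
       layers = lay,
       Wo = .glorot(units, vocabSize),
       bo = rep(0, vocabSize))
}

.lstmCell <- function(lp, x, h, c, U) {
  z <- x %*% lp$W + h %*% lp$U
  z <- sweep(z, 2L, lp$b, `+`)
  i <- .sigm(z[, 1:U, drop = FALSE])
  f <- .sigm(z[, (U + 1):(2 * U), drop = FALSE])
  g <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
  o <- .sigm(z[, (3 * U + 1):(4 * U), drop = FALSE])
  cn <- f * c + i * g
  tc <- tanh(cn)
  list(h = o * tc, c = cn, i = i, f = f, g = g, o = o, tc = tc)
}

# Xin: B x T matrix of 1-based token codes (inputs; targets handled by caller)
.lstmForwardR <- function(params, Xin) {
  B <- nrow(Xin); T_ <- ncol(Xin)
  L <- length(params$layers)
  U <- nrow(params$Wo)
  h <- rep(list(matrix(0, B, U)), L)
  c <- rep(list(matrix(0, B, U)), L)
  probs <- vector("list", T_)
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- params$emb[Xin[, t], , drop = FALSE]
    step <- vector("list", L)
    inp <- x
    for (l in seq_len(L)) {
      cell <- .lstmCell(params$layers[[l]], inp, h[[l]], c[[l]], U)
      step[[l]] <- c(cell, list(xin = inp, hprev = h[[l]], cprev = c[[l]]))
      h[[l]] <- cell$h
      c[[l]] <- cell$c
      inp <- cell$h
    }
    logits <- sweep(h[[L]] %*% params$Wo, 2L, params$bo, `+`)
    probs[[t]] <- .softmaxRows(logits)
    cache[[t]] <- step
  }
  list(probs = probs, cache = cache, state = list(h = h, c = c))
}

# dlogits: list of B x V matrices (one per step); returns gradient tree
.lstmBackwardR <- function(params, Xin, fwd, dlogits) {
  B <- nrow(Xin); T_ <- ncol(Xin)
  L <- length(params$layers)
  U <- nrow(params$Wo)
  g <- .treeZero(params)
  dh <- rep(list(matrix(0, B, U)), L)
  dc <- rep(list(matrix(0, B, U)), L)
  dxEmb <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    step <- fwd$cache[[t]]
    dl <- dlogits[[t]]
    g$Wo <- g$Wo + crossprod(step[[L]]$h, dl)
    g$bo <- g$bo + colSums(dl)
    dtop <- dl %*% t(params$Wo)
    for (l in rev(seq_len(L))) {
      s <- step[[l]]
      dht <- dh[[l]] + if (l == L) dtop else dlow
      do_ <- dht * s$tc
      dct <- dc[[l]] + dht * s$o * (1 - s$tc^2)
      di <- dct * s$g
      df <- dct * s$cprev
      dg <- dct * s$i
      dc[[l]] <- dct * s$f
      dz <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do_ * s$o * (1 - s$o))
      lp <- params$layers[[l]]
      g$layers[[l]]$W <- g$layers[[l]]$W + crossprod(s$xin, dz)
      g$layers[[l]]$U <- g$layers[[l]]$U + crossprod(s$hprev, dz)
      g$layers[[l]]$b <- g$layers[[l]]$b + colSums(dz)
      dh[[l]] <- dz %*% t(lp$U)
      dlow <- dz %*% t(lp$W)
    }
    dxEmb[[t]] <- dlow
  }
  toks <- as.vector(Xin)
  dxs <- do.call(rbind, dxEmb)
  rs <- rowsum(dxs, group = toks)
  ids <- as.integer(rownames(rs))
  g$emb[ids, ] <- g$emb[ids, , drop = FALSE] + rs
  g
}

.lstmStateInit <- function(params, B) {
  L <- length(params$layers)
  U <- nrow(params$Wo)
  list(h = rep(list(matrix(0, B, U)), L),
       c = rep(list(matrix(0, B, U)), L))
}

# one autoregressive step; tokens: B 1-based codes
.lstmStep <- function(params, tokens, state) {
  L <- length(params$layers)
  U <- nrow(params$Wo)
  inp <- params$emb[tokens, , drop = FALSE]
  for (l in seq_len(L)) {
    cell <- .lstmCell(params$layers[[l]], inp, state$h[[l]], state$c[[l]], U)
    state$h[[l]] <- cell$h
    state$c[[l]] <- cell$c
    inp <- cell$h
  }
  logits <- sweep(state$h[[L]] %*% params$Wo, 2L, params$bo, `+`)
  list(logits = logits, state = state)
}

# ---- GRU (predictor backbone) ----------------------------------------------

.gruInitParams <- function(nin, units) {
  list(W = .glorot(nin, 3L * units),
       Uzr = .glorot(units, 2L * units),
       Un = .glorot(units, units),
       b = rep(0, 3L * units))
}

# xs: list of T matrices (B x nin); returns hs (list of B x U) + cache
.gruForwardR <- function(p, xs) {
  T_ <- length(xs)
  B <- nrow(xs[[1]])
  U <- ncol(p$Un)
  h <- matrix(0, B, U)
  hs <- vector("list", T_)
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- xs[[t]]
    zr <- x %*% p$W[, 1:(2 * U), drop = FALSE] + h %*% p$Uzr
    zr <- sweep(zr, 2L, p$b[1:(2 * U)], `+`)
    z <- .sigm(zr[, 1:U, drop = FALSE])
    r <- .sigm(zr[, (U + 1):(2 * U), drop = FALSE])
    npre <- x %*% p$W[, (2 * U + 1):(3 * U), drop = FALSE] + (r * h) %*% p$Un
    npre <- sweep(npre, 2L, p$b[(2 * U + 1):(3 * U)], `+`)
    n <- tanh(npre)
    hn <- (1 - z) * n + z * h
    cache[[t]] <- list(x = x, hprev = h, z = z, r = r, n = n)
    h <- hn
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

# dhs: list of T upstream gradients on hs (B x U, zeros allowed)
.gruBackwardR <- function(p, fwd, dhs) {
  T_ <- length(fwd$cache)
  U <- ncol(p$Un)
  g <- .treeZero(p)
  B <- nrow(dhs[[1]])
  carry <- matrix(0, B, U)
  dxs <- vector("list", T_)
  Wz <- p$W[, 1:(2 * U), drop = FALSE]
  Wn <- p$W[, (2 * U + 1):(3 * U), drop = FALSE]
  for (t in rev(seq_len(T_))) {
    s <- fwd$cache[[t]]
    dh <- dhs[[t]] + carry
    dz <- dh * (s$hprev - s$n)
    dn <- dh * (1 - s$z)
    carry <- dh * s$z
    dnpre <- dn * (1 - s$n^2)
    g$W[, (2 * U + 1):(3 * U)] <- g$W[, (2 * U + 1):(3 * U)] +
      crossprod(s$x, dnpre)
    g$Un <- g$Un + crossprod(s$r * s$hprev, dnpre)
    g$b[(2 * U + 1):(3 * U)] <- g$b[(2 * U + 1):(3 * U)] + colSums(dnpre)
    tmp <- dnpre %*% t(p$Un)
    dr <- tmp * s$hprev
    carry <- carry + tmp * s$r
    dzpre <- dz * s$z * (1 - s$z)
    drpre <- dr * s$r * (1 - s$r)
    dzr <- cbind(dzpre, drpre)
    g$W[, 1:(2 * U)] <- g$W[, 1:(2 * U)] + crossprod(s$x, dzr)
    g$Uzr <- g$Uzr + crossprod(s$hprev, dzr)
    g$b[1:(2 * U)] <- g$b[1:(2 * U)] + colSums(dzr)
    carry <- carry + dzr %*% t(p$Uzr)
    dxs[[t]] <- dnpre %*% t(Wn) + dzr %*% t(Wz)
  }
  list(grads = g, dxs = dxs)
}

# ---- additive attention pooling --------------------------------------------

.attnInitParams <- function(dim) {
  list(q = stats::runif(dim, -sqrt(6 / (dim + 1)), sqrt(6 / (dim + 1))),
       b = 0)
}

# hs: list of T hidden matrices (B x D); alpha = softmax_t(tanh(h_t q + b))
.attnForward <- function(p, hs) {
  T_ <- length(hs)
  B <- nrow(hs[[1]])
  E <- matrix(0, B, T_)
  for (t in seq_len(T_)) E[, t] <- hs[[t]] %*% p$q + p$b
  S <- tanh(E)
  alpha <- .softmaxRows(S)
  ctx <- matrix(0, B, ncol(hs[[1]]))
  for (t in seq_len(T_)) ctx <- ctx + alpha[, t] * hs[[t]]
  list(context = ctx, alpha = alpha, S = S, hs = hs)
}

.attnBackward <- function(p, fwd, dctx) {
  T_ <- length(fwd$hs)
  alpha <- fwd$alpha
  dalpha <- matrix(0, nrow(dctx), T_)
  dhs <- vector("list", T_)
  for (t in seq_len(T_)) {
    dalpha[, t] <- rowSums(dctx * fwd$hs[[t]])
    dhs[[t]] <- alpha[, t] * dctx
  }
  dS <- alpha * (dalpha - rowSums(alpha * dalpha))
  dE <- dS * (1 - fwd$S^2)
  gq <- numeric(length(p$q))
  for (t in seq_len(T_)) {
    gq <- gq + as.vector(crossprod(fwd$hs[[t]], dE[, t]))
    dhs[[t]] <- dhs[[t]] + outer(dE[, t], p$q)
  }
  list(grads = list(q = gq, b = sum(dE)), dhs = dhs)
}

# ---- numerical gradient check (used by the tests) --------------------------

.numericGradient <- function(lossFn, params, eps = 1e-5) {
  # central differences over every scalar entry of the parameter tree
  flatSet <- function(tree, path, idx, val) {
    if (length(path) == 0) {
      tree[idx] <- val
      return(tree)
    }
    tree[[path[1]]] <- flatSet(tree[[path[1]]], path[-1], idx, val)
    tree
  }
  walk <- function(tree, path) {
    if (is.list(tree))
      return(lapply(seq_along(tree), function(i) walk(tree[[i]], c(path, i))))
    out <- tree * 0
    for (i in seq_along(tree)) {
      up <- flatSet(params, path, i, tree[i] + eps)
      dn <- flatSet(params, path, i, tree[i] - eps)
      out[i] <- (lossFn(up) - lossFn(dn)) / (2 * eps)
    }
    out
  }
  walk(params, integer(0))
}

# ---- compiled dispatchers ---------------------------------------------------
# The Rcpp kernels in src/rnn_kernels.cpp are the production path; the *R
# reference implementations above define the semantics and back the
# cross-checks in the test suite.

.listToCube <- function(lst) {
  T_ <- length(lst)
  arr <- array(0, c(nrow(lst[[1]]), ncol(lst[[1]]), T_))
  for (t in seq_len(T_)) arr[, , t] <- lst[[t]]
  arr
}

.cubeToList <- function(arr) {
  lapply(seq_len(dim(arr)[3]), function(t) arr[, , t, drop = FALSE][, , 1, drop = FALSE][, , 1])
}

.lstmForward <- function(params, Xin) {
  f <- .cpp_lstm_forward(params, Xin)
  T_ <- ncol(Xin)
  probs <- lapply(seq_len(T_), function(t) matrix(f$P[, , t], nrow(Xin)))
  list(probs = probs, cpp = f,
       state = list(h = f$h, c = f$c))
}

.lstmBackward <- function(params, Xin, fwd, dlogits) {
  dl <- .listToCube(dlogits)
  g <- .cpp_lstm_backward(params, Xin, fwd$cpp, dl)
  g$bo <- as.numeric(g$bo)
  for (l in seq_along(g$layers)) g$layers[[l]]$b <- as.numeric(g$layers[[l]]$b)
  g
}

.gruForward <- function(p, xs) {
  X <- .listToCube(xs)
  f <- .cpp_gru_forward(p, X)
  B <- dim(X)[1]
  hs <- lapply(seq_len(dim(X)[3]), function(t) matrix(f$hs[, , t], B))
  list(hs = hs, cpp = f)
}

.gruBackward <- function(p, fwd, dhs) {
  d <- .listToCube(dhs)
  r <- .cpp_gru_backward(p, fwd$cpp, d)
  B <- dim(d)[1]
  r$grads$b <- as.numeric(r$grads$b)
  dxs <- lapply(seq_len(dim(r$dxs)[3]), function(t) matrix(r$dxs[, , t], B))
  list(grads = r$grads, dxs = dxs)
}
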