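# Hit selection: Pareto partitioning of (pIC50, SAS) solutions, stereoisomer
# enumeration over unassigned tetrahedral centers, similarity analysis
# (fingerprint Tanimoto and maximum-common-substructure Tanimoto) and
# attention-based per-atom interpretability maps.

#' Pareto partition of candidate solutions
#'
#' Objectives: maximize \code{pic50}, minimize \code{sas}. A solution is
#' dominated when another is at least as good on both axes and strictly
#' better on one (weak dominance); exact ties on both axes are all retained
#' in the front. Implemented as a sort-and-sweep, O(n log n).
#'
#' @param solutions data.frame with columns \code{smiles}, \code{pic50},
#'   \code{sas} (>= 1 row, finite values).
#' @return list with data.frames \code{front} (non-dominated) and
#'   \code{dominated}; the partition is exhaustive and disjoint.
#' @export
paretoFront <- function(solutions) {
  if (!nrow(solutions)) stop("no solutions")
  stopifnot(all(c("pic50", "sas") %in% names(solutions)))
  if (any(!is.finite(solutions$pic50)) || any(!is.finite(solutions$sas)))
    stop("solutions must have finite objectives")
  n <- nrow(solutions)
  ord <- order(-solutions$pic50, solutions$sas)
  dominated <- logical(n)
  bestSas <- Inf        # min sas among strictly-better-pic50 rows
  i <- 1L
  while (i <= n) {
    # group of equal pic50
    j <- i
    p <- solutions$pic50[ord[i]]
    while (j < n && solutions$pic50[ord[j + 1L]] == p) j <- j + 1L
    grp <- ord[i:j]
    gmin <- min(solutions$sas[grp])
    for (k in grp) {
      s <- solutions$sas[k]
      dominated[k] <- (s >= bestSas) || (s > gmin)
    }
    bestSas <- min(bestSas, gmin)
    i <- j + 1L
  }
  list(front = solutions[!dominated, , drop = FALSE],
       dominated = solutions[dominated, , drop = FALSE])
}

#' Set of stereoisomers of a parent molecule
#'
#' @slot parent canonical SMILES of the parent.
#' @slot nCenters number of unassigned tetrahedral stereocenters found.
#' @slot isomers data.frame with column \code{smiles} (isomeric canonical
#'   SMILES) and, after ranking, \code{pic50}, \code{sas}, \code{rank}.
#' @slot best index of the top-ranked isomer (NA before ranking).
#' @exportClass StereoisomerSet
setClass("StereoisomerSet",
  representation(parent = "character", nCenters = "integer",
                 isomers = "data.frame", best = "integer"))

setMethod("show", "StereoisomerSet", function(object) {
  cat("StereoisomerSet:", object@parent, "\n ", object@nCenters,
      "unassigned centers ->", nrow(object@isomers), "isomers\n")
  if (!is.na(object@best))
    cat("  best:", object@isomers$smiles[object@best], "\n")
})

#' Isomer table of a stereoisomer set
#' @param set a \linkS4class{StereoisomerSet}.
#' @return data.frame of isomers.
#' @export
isomerTable <- function(set) set@isomers

#' Enumerate stereoisomers over unassigned tetrahedral centers
#'
#' Detects unassigned tetrahedral stereocenters (sp3 carbons with four
#' distinguishable substituents and no stereo annotation), enumerates all
#' \eqn{2^c} chirality assignments by rewriting the corresponding atom tokens
#' (\code{C} to \code{[C@H]}/\code{[C@@H]} or \code{[C@]}/\code{[C@@]}), and
#' deduplicates by canonical isomeric SMILES, so symmetric (meso) collapses
#' leave at most \eqn{2^c} distinct isomers. Double-bond geometry and
#' already-assigned centers are left untouched.
#'
#' @param smiles a single valid SMILES.
#' @param maxCenters safety cap on enumerated centers.
#' @return a \linkS4class{StereoisomerSet}.
#' @export
enumerateStereoisomers <- function(smiles, maxCenters = 10L) {
  rec <- canonicalizeSmiles(smiles)
  if (!rec$valid[1]) stop("invalid molecule: ", smiles)
  parent <- rec$smiles_canonical[1]
  g <- molGraphs(parent)[[1]]
  if (is.null(g)) stop("could not build molecular graph for ", parent)
  sc <- .stereoCenters(g)
  un <- which(!sc$assigned)
  c_ <- length(un)
  if (c_ > maxCenters)
    stop(c_, " unassigned centers exceed maxCenters = ", maxCenters)
  if (c_ == 0L) {
    return(new("StereoisomerSet", parent = parent, nCenters = 0L,
               isomers = data.frame(smiles = parent, stringsAsFactors = FALSE),
               best = NA_integer_))
  }
  atomIdx <- sc$idx[un]
  tokPos <- g$atomTokenPos[atomIdx]
  hasH <- sc$implicitH[un] == 1L
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), c_))
  variants <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    toks <- g$tokens
    for (k in seq_len(c_)) {
      at <- if (combos[r, k]) "@@" else "@"
      toks[tokPos[k]] <- if (hasH[k]) paste0("[C", at, "H]")
                         else paste0("[C", at, "]")
    }
    variants[r] <- paste(toks, collapse = "")
  }
  vrec <- canonicalizeSmiles(variants)
  iso <- unique(vrec$smiles_canonical[vrec$valid])
  new("StereoisomerSet", parent = parent, nCenters = as.integer(c_),
      isomers = data.frame(smiles = iso, stringsAsFactors = FALSE),
      best = NA_integer_)
}

#' Rank stereoisomers by predicted potency
#'
#' Scores each isomer with the predictor (isomeric canonical SMILES; a
#' stereo-aware vocabulary distinguishes \code{@}/\code{@@} tokens) and ranks
#' by predicted pIC50 descending; the synthetic accessibility of each isomer
#' is reported alongside so the affinity/synthesizability trade-off stays
#' visible. No composite score is applied.
#'
#' @param set a \linkS4class{StereoisomerSet}.
#' @param predictor a trained \linkS4class{Pic50Predictor}.
#' @return the set with scored, ranked isomers and \code{best} set.
#' @export
rankStereoisomers <- function(set, predictor) {
  iso <- set@isomers
  pred <- predictPic50(predictor, iso$smiles)
  iso$pic50 <- pred$pic50
  iso$sas <- syntheticAccessibility(iso$smiles)
  iso$rank <- rank(-iso$pic50, ties.method = "first")
  iso <- iso[order(iso$rank), , drop = FALSE]
  rownames(iso) <- NULL
  set@isomers <- iso
  set@best <- 1L
  set
}

#' Fingerprint and maximum-common-substructure similarity
#'
#' \code{t_s} is the ECFP4 Tanimoto similarity. \code{t_mcs} is the Tanimoto
#' index on atom counts of the maximum common (induced, element- and
#' bond-order-matched) substructure:
#' \eqn{|MCS| / (|A| + |B| - |MCS|)}, found as a maximum clique of the
#' modular product graph. A search exceeding \code{timeout} seconds reports
#' \code{t_mcs = NA} with \code{mcs_timeout = TRUE}.
#'
#' @param smilesA,smilesB valid SMILES strings.
#' @param nbits fingerprint length.
#' @param timeout MCS time budget in seconds.
#' @return list with \code{t_s}, \code{t_mcs}, \code{mcs_timeout}.
#' @export
similarityReport <- function(smilesA, smilesB, nbits = 2048, timeout = 10) {
  recs <- canonicalizeSmiles(c(smilesA, smilesB))
  if (!all(recs$valid)) stop("both molecules must be valid")
  can <- recs$smiles_canonical
  t_s <- tanimoto(ecfp(can[1], 2, nbits), ecfp(can[2], 2, nbits))
  gs <- molGraphs(can)
  gA <- gs[[1]]; gB <- gs[[2]]
  nA <- length(gA$elements); nB <- length(gB$elements)
  bondMat <- function(g, n) {
    m <- matrix(0, n, n)
    if (nrow(g$bonds)) {
      m[g$bonds[, 1:2, drop = FALSE]] <- g$bonds[, 3]
      m[g$bonds[, 2:1, drop = FALSE]] <- g$bonds[, 3]
    }
    m
  }
  bA <- bondMat(gA, nA); bB <- bondMat(gB, nB)
  pairs <- which(outer(gA$elements, gB$elements, `==`), arr.ind = TRUE)
  if (!nrow(pairs))
    return(list(t_s = t_s, t_mcs = 0, mcs_timeout = FALSE))
  np <- nrow(pairs)
  edges <- integer(0)
  for (u in seq_len(np - 1L)) {
    a1 <- pairs[u, 1]; b1 <- pairs[u, 2]
    vs <- (u + 1L):np
    ok <- pairs[vs, 1] != a1 & pairs[vs, 2] != b1 &
      bA[a1, pairs[vs, 1]] == bB[b1, pairs[vs, 2]]
    if (any(ok)) edges <- c(edges, rbind(u, vs[ok]))
  }
  mcsSize <- tryCatch({
    setTimeLimit(elapsed = timeout, transient = TRUE)
    on.exit(setTimeLimit(elapsed = Inf, transient = TRUE), add = TRUE)
    gprod <- igraph::make_empty_graph(n = np, directed = FALSE)
    if (length(edges))
      gprod <- igraph::add_edges(gprod, edges)
    igraph::clique_num(gprod)
  }, error = function(e) NA_integer_)
  if (is.na(mcsSize))
    return(list(t_s = t_s, t_mcs = NA_real_, mcs_timeout = TRUE))
  list(t_s = t_s, t_mcs = mcsSize / (nA + nB - mcsSize), mcs_timeout = FALSE)
}

#' Project token-level attention onto atoms
#'
#' Atom tokens keep their attention weight; each non-atom token's weight is
#' split equally between the nearest preceding and following atom tokens
#' (boundary tokens assign all mass to their single neighbor). The resulting
#' per-atom weights sum to 1 and highlight candidate interaction regions.
#'
#' @param predictor a trained attention-bearing \linkS4class{Pic50Predictor}.
#' @param smiles a single valid SMILES.
#' @return data.frame with \code{atom} (index in canonical atom order),
#'   \code{element}, \code{weight}, sorted by atom index.
#' @export
attentionAtomMap <- function(predictor, smiles) {
  aw <- attentionWeights(predictor, smiles)
  toks <- aw$tokens
  alphas <- aw$alphas
  isAtom <- .isAtomToken(toks)
  if (!any(isAtom)) stop("no atom tokens in ", smiles)
  atomPos <- which(isAtom)
  w <- numeric(length(atomPos))
  names(w) <- as.character(atomPos)
  for (k in seq_along(toks)) {
    if (isAtom[k]) {
      w[as.character(k)] <- w[as.character(k)] + alphas[k]
    } else {
      prev <- atomPos[atomPos < k]
      nxt <- atomPos[atomPos > k]
      if (length(prev) && length(nxt)) {
        w[as.character(max(prev))] <- w[as.character(max(prev))] + alphas[k] / 2
        w[as.character(min(nxt))] <- w[as.character(min(nxt))] + alphas[k] / 2
      } else if (length(prev)) {
        w[as.character(max(prev))] <- w[as.character(max(prev))] + alphas[k]
      } else {
        w[as.character(min(nxt))] <- w[as.character(min(nxt))] + alphas[k]
      }
    }
  }
  w <- w / sum(w)
  g <- molGraphs(aw$smiles)[[1]]
  elements <- if (!is.null(g) &&
                  length(g$elements) == length(atomPos)) g$elements
              else sub("^\\[", "", substr(toks[atomPos], 1, 2))
  data.frame(atom = seq_along(atomPos), element = elements,
             weight = unname(w), stringsAsFactors = FALSE)
}
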