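# Synthetic accessibility scoring. The score follows the classic
# fragment-contribution-plus-complexity recipe: a rarity term over circular
# atom environments (estimated against an internal reference set of drug-like
# molecules built by the fixture assembler) plus penalties for molecular size,
# ring systems and stereocenters, affinely mapped onto the conventional 1
# (easy to make) .. 10 (practically impossible) scale.

.hitgenCache <- new.env(parent = emptyenv())

.atomEnvironments <- function(g, radius = 2L) {
  # iterative Morgan-style labels; returns character matrix [atom, radius+1]
  n <- length(g$elements)
  adj <- .graphAdjacency(g)
  ords <- vector("list", n)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      a <- g$bonds[r, 1]; b <- g$bonds[r, 2]; o <- g$bonds[r, 3]
      ords[[a]] <- c(ords[[a]], o)
      ords[[b]] <- c(ords[[b]], o)
    }
  }
  impH <- .implicitH(g)
  lab <- paste0(g$elements, ifelse(g$aromatic, "a", ""), ":",
                lengths(adj), ":", impH)
  out <- matrix("", n, radius + 1L)
  out[, 1L] <- lab
  cur <- lab
  if (radius > 0) for (r in seq_len(radius)) {
    nxt <- character(n)
    for (a in seq_len(n)) {
      nb <- adj[[a]]
      nbl <- if (length(nb)) sort(paste0(ords[[a]], "|", cur[nb])) else character(0)
      nxt[a] <- paste0(cur[a], "(", paste(nbl, collapse = ","), ")")
    }
    out[, r + 1L] <- nxt
    cur <- nxt
  }
  out
}

.sasReferenceCounts <- function() {
  if (!is.null(.hitgenCache$sasRef)) return(.hitgenCache$sasRef)
  smis <- .assembleMolecules(300, seed = 20260101L)
  # common aliphatic/small-molecule environments, weighted up so that simple
  # chains score as easy even against an aryl-rich reference
  simple <- rep(c("CCO", "CCC", "CCCC", "CCCCC", "CC(C)C", "CCN", "CCCN",
                  "CCOC", "CCOCC", "CC(C)O", "CCC(=O)O", "CC(=O)OC",
                  "CC(=O)NC", "CCS", "OCCO", "NCCN", "OCCN", "CC(C)(C)C",
                  "C1CCCCC1", "C1CCCC1", "CC1CCCCC1", "OC1CCCCC1"), 8L)
  smis <- c(smis, simple)
  rec <- canonicalizeSmiles(smis)
  graphs <- molGraphs(rec$smiles_canonical[rec$valid])
  envs <- unlist(lapply(graphs, function(g) {
    if (is.null(g)) return(character(0))
    as.vector(.atomEnvironments(g, 2L))
  }))
  tab <- table(envs)
  ref <- list(counts = as.integer(tab), keys = names(tab), total = length(envs))
  .hitgenCache$sasRef <- ref
  ref
}

.stereoCenters <- function(g) {
  # candidate tetrahedral stereocenters: sp3 carbons whose (up to four)
  # substituent branches, implicit hydrogen included, are pairwise distinct
  n <- length(g$elements)
  adj <- .graphAdjacency(g)
  ordm <- matrix(0, n, n)
  if (nrow(g$bonds)) {
    ordm[g$bonds[, 1:2, drop = FALSE]] <- g$bonds[, 3]
    ordm[g$bonds[, 2:1, drop = FALSE]] <- g$bonds[, 3]
  }
  impH <- .implicitH(g)
  res <- list(idx = integer(0), assigned = logical(0), implicitH = integer(0))
  if (!n) return(res)
  bondOrder <- function(a, b) ordm[a, b]
  branchHash <- function(start, blocked) {
    # BFS levels from `start` with the center removed
    seen <- logical(n); seen[blocked] <- TRUE; seen[start] <- TRUE
    frontier <- start
    parts <- paste0(g$elements[start], ifelse(g$aromatic[start], "a", ""))
    depth <- 0L
    while (length(frontier) && depth < 8L) {
      nxt <- integer(0)
      codes <- character(0)
      for (a in frontier) for (b in adj[[a]]) if (!seen[b]) {
        seen[b] <- TRUE
        nxt <- c(nxt, b)
        codes <- c(codes, paste0(g$elements[b],
                                 ifelse(g$aromatic[b], "a", ""),
                                 bondOrder(a, b)))
      }
      if (length(codes)) parts <- c(parts, paste(sort(codes), collapse = "."))
      frontier <- nxt
      depth <- depth + 1L
    }
    paste(parts, collapse = "/")
  }
  for (a in seq_len(n)) {
    if (g$elements[a] != "C" || g$aromatic[a]) next
    nb <- adj[[a]]
    deg <- length(nb)
    h <- impH[a]
    if (!((deg == 3L && h == 1L) || (deg == 4L && h == 0L))) next
    if (any(vapply(nb, function(b) bondOrder(a, b) != 1, logical(1)))) next
    hashes <- vapply(nb, branchHash, character(1), blocked = a)
    if (h == 1L) hashes <- c(hashes, "H")
    if (anyDuplicated(hashes)) next
    tokpos <- g$atomTokenPos[a]
    assigned <- !is.na(tokpos) && grepl("@", g$tokens[tokpos], fixed = TRUE)
    res$idx <- c(res$idx, a)
    res$assigned <- c(res$assigned, assigned)
    res$implicitH <- c(res$implicitH, h)
  }
  res
}

#' Synthetic accessibility score
#'
#' Heuristic 1-10 score of how hard a molecule is to synthesize. The score is
#' the sum of (i) a fragment rarity term, the mean negative log-frequency of
#' each atom's radius-2 circular environment in an internal reference set of
#' drug-like molecules, and (ii) complexity penalties for molecular size, ring
#' count and stereocenters, rescaled to [1, 10] and clipped. Deterministic for
#' a fixed canonical SMILES.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric vector of scores in [1, 10] (NA where the molecular graph
#'   could not be built).
#' @examples
#' \donttest{syntheticAccessibility(c("CCO", "CC1CCC2CC(C)C(C)CC2C1C"))}
#' @export
syntheticAccessibility <- function(smiles) {
  if (!length(smiles)) return(numeric(0))
  ref <- .sasReferenceCounts()
  graphs <- molGraphs(smiles)
  vapply(graphs, function(g) {
    if (is.null(g)) return(NA_real_)
    envs <- .atomEnvironments(g, 2L)[, 3L]
    cnt <- ref$counts[match(envs, ref$keys)]
    cnt[is.na(cnt)] <- 0L
    rarity <- mean(-log10((cnt + 0.5) / (ref$total + 0.5)))
    counts <- .countSubstructures(g)
    nStereo <- length(.stereoCenters(g)$idx)
    nHeavy <- counts$nHeavy
    sizePen <- nHeavy^1.005 - nHeavy
    ringPen <- 0.35 * log2(counts$nRings + 1)
    stereoPen <- 0.7 * log2(nStereo + 1)
    raw <- rarity + sizePen + ringPen + stereoPen
    # observed raw spans roughly [2, 9] from simple chains to dense
    # polycyclic stereo-rich frames; affine map onto the 1-10 convention
    min(10, max(1, 1 + 9 * (raw - 2.0) / 7.0))
  }, numeric(1))
}
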