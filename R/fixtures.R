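# Synthetic fixtures: self-contained drug-like corpora and affinity tables.
# Molecules are assembled by combinatorial decoration of aryl/alicyclic
# scaffolds with linkers and tail groups, which guarantees syntactic validity
# and (after filtering) the drug-like MW/logP window. The affinity oracle is
# linear in interpretable substructure counts so that regression and
# attention-interpretability tests have a known ground truth.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.fixtureFragments <- function() {
  list(
    left = c("c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(Br)cc1",
             "c1ccc(C)cc1", "c1ccc(OC)cc1", "c1ccc2ccccc2c1", "c1ccncc1",
             "C1CCCCC1", "c1ccc(N(C)C)cc1"),
    linker = c("C(=O)N", "NC(=O)", "CC(O)", "CC(O)C", "CN", "CC(C)N",
               "S(=O)(=O)N", "CNC(=O)", "CC(O)CC(C)", "N(C)C(=O)",
               "OCC(O)", "CC"),
    right = c("c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(C)cc1",
              "c1ccc(OC)cc1", "c1ccncc1", "C1CCCCC1", "c1ccc2ccccc2c1",
              "c1ccc(N)cc1", "c1ccc(O)cc1"),
    tail = c("", "C", "CC", "O", "N", "OC")
  )
}

# raw combinatorial assembly (pre-filter); deterministic under seed
.assembleMolecules <- function(n, seed) {
  fr <- .fixtureFragments()
  capacity <- prod(lengths(fr))
  if (n > capacity)
    stop("requested ", n, " molecules but the scaffold space holds only ",
         capacity, "; reduce n or extend the fragment sets")
  .withSeed(seed, {
    idx <- sample.int(capacity, capacity)
  })
  dims <- lengths(fr)
  pick <- arrayInd(idx, dims)
  smis <- paste0(fr$left[pick[, 1]], fr$linker[pick[, 2]],
                 fr$right[pick[, 3]], fr$tail[pick[, 4]])
  unique(smis)[seq_len(min(n, length(unique(smis))))]
}

#' Generate a synthetic drug-like SMILES corpus
#'
#' Combinatorial decoration of aromatic/alicyclic scaffolds with linkers
#' (amides, amines, sulfonamides, hydroxyalkyl chains carrying unassigned
#' stereocenters) and tail groups. Every returned molecule is valid, canonical
#' and inside the drug-like training window (MW 200-600 g/mol, logP -2..6).
#' Identical \code{n}/\code{seed} give byte-identical output.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @return character vector of \code{n} canonical SMILES.
#' @examples
#' \donttest{head(makeCorpus(50, seed = 1))}
#' @export
makeCorpus <- function(n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  fr <- .fixtureFragments()
  capacity <- prod(lengths(fr))
  key <- paste0("corpus_", seed)
  cache <- .hitgenCache[[key]]
  if (is.null(cache)) {
    raw <- .assembleMolecules(capacity, seed)  # full shuffled space, unfiltered
    cache <- list(raw = raw, consumed = 0L, kept = character(0))
  }
  # filter lazily in chunks so small requests stay cheap; the kept prefix is
  # identical whatever n is asked for
  while (length(cache$kept) < n && cache$consumed < length(cache$raw)) {
    take <- seq.int(cache$consumed + 1L,
                    min(cache$consumed + max(2L * (n - length(cache$kept)), 200L),
                        length(cache$raw)))
    rec <- canonicalizeSmiles(cache$raw[take])
    rec <- rec[rec$valid, , drop = FALSE]
    rec <- computeDescriptors(rec, sas = FALSE)
    rec <- filterTrainingSet(rec)
    new <- setdiff(rec$smiles_canonical, cache$kept)
    cache$kept <- c(cache$kept, new)
    cache$consumed <- max(take)
  }
  .hitgenCache[[key]] <- cache
  if (length(cache$kept) < n)
    stop("requested ", n, " molecules but only ", length(cache$kept),
         " pass the drug-like filter; scaffold capacity is ", capacity)
  cache$kept[seq_len(n)]
}

#' Structure-to-affinity oracle for synthetic labels
#'
#' Deterministic pseudo-pIC50: a linear combination of substructure counts
#' (nitrogen atoms, aromatic rings, halogens, amide groups) plus optional
#' Gaussian noise. Used to label fixture datasets with a signal a regressor
#' can provably recover.
#'
#' @param smiles character vector of valid SMILES.
#' @param coefficients named numeric vector with entries \code{nN},
#'   \code{nAromRings}, \code{nHal}, \code{nAmide} (the halogen term is
#'   subtracted).
#' @param intercept baseline value.
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param seed seed for the noise (ignored when \code{noiseSd = 0}).
#' @return numeric vector of labels.
#' @export
affinityOracle <- function(smiles,
                           coefficients = c(nN = 0.5, nAromRings = 0.4,
                                            nHal = 0.3, nAmide = 0.6),
                           intercept = 4, noiseSd = 0, seed = 1L) {
  rec <- canonicalizeSmiles(smiles)
  if (!all(rec$valid)) stop("invalid SMILES passed to the affinity oracle")
  graphs <- molGraphs(smiles)
  if (any(vapply(graphs, is.null, logical(1))))
    stop("invalid SMILES passed to the affinity oracle")
  base <- vapply(graphs, function(g) {
    cs <- .countSubstructures(g)
    intercept + coefficients[["nN"]] * cs$nN +
      coefficients[["nAromRings"]] * cs$nAromRings -
      coefficients[["nHal"]] * cs$nHal +
      coefficients[["nAmide"]] * cs$nAmide
  }, numeric(1))
  if (noiseSd > 0)
    base <- base + .withSeed(seed, stats::rnorm(length(base), 0, noiseSd))
  base
}

#' Build a synthetic affinity table
#'
#' \code{n} unique fixture molecules labelled by the affinity oracle. The
#' deterministic labels are affinely rescaled to span [4, 10] pIC50 units;
#' Gaussian noise (in pIC50 units) is added afterwards and the result clipped
#' back to [4, 10]. The default size mirrors a typical augmented
#' target-affinity set of ~1450 compounds.
#'
#' @param n number of rows (default 1453).
#' @param seed integer seed.
#' @param noiseSd label noise in pIC50 units (default 0.3).
#' @param coefficients,intercept forwarded to \code{\link{affinityOracle}}.
#' @return data.frame with columns \code{smiles}, \code{pic50}; no duplicate
#'   canonical SMILES.
#' @export
makeAffinityTable <- function(n = 1453, seed = 1L, noiseSd = 0.3,
                              coefficients = c(nN = 0.5, nAromRings = 0.4,
                                               nHal = 0.3, nAmide = 0.6),
                              intercept = 4) {
  smis <- makeCorpus(n, seed = seed)
  y0 <- affinityOracle(smis, coefficients = coefficients,
                       intercept = intercept, noiseSd = 0)
  rng <- range(y0)
  y <- if (diff(rng) > 0) 4 + 6 * (y0 - rng[1]) / diff(rng) else rep(7, n)
  if (noiseSd > 0)
    y <- y + .withSeed(seed + 7L, stats::rnorm(n, 0, noiseSd))
  data.frame(smiles = smis, pic50 = pmin(10, pmax(4, y)),
             stringsAsFactors = FALSE)
}
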