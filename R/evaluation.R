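# Distribution-learning metrics for generated molecule sets: validity,
# uniqueness, novelty, internal/external Tanimoto diversity, a KL-divergence
# score over physicochemical descriptor distributions, and before/after
# property-shift reports for conditioned generation.

#' Fraction of syntactically valid molecules
#'
#' @param sample non-empty character vector of raw SMILES.
#' @return fraction passing the canonicalization oracle.
#' @export
validity <- function(sample) {
  if (!length(sample)) stop("empty sample")
  ok <- nzchar(sample)
  res <- logical(length(sample))
  if (any(ok)) res[ok] <- canonicalizeSmiles(sample[ok])$valid
  mean(res)
}

#' Uniqueness and novelty of a generated sample
#'
#' Uniqueness is the fraction of valid molecules that are distinct (on
#' canonical SMILES); novelty is the fraction of the distinct molecules absent
#' from the training corpus (also compared on canonical forms).
#'
#' @param sample character vector of raw SMILES.
#' @param corpus training corpus (canonicalized internally).
#' @return list with \code{uniqueness}, \code{novelty} (NA, flagged, when no
#'   molecule is valid).
#' @export
uniquenessNovelty <- function(sample, corpus) {
  ok <- nzchar(sample)
  rec <- if (any(ok)) canonicalizeSmiles(sample[ok])
         else data.frame(valid = logical(0), smiles_canonical = character(0))
  can <- rec$smiles_canonical[rec$valid]
  if (!length(can))
    return(list(uniqueness = NA_real_, novelty = NA_real_, nValid = 0L))
  uniq <- unique(can)
  corpusCan <- canonicalizeSmiles(corpus)
  corpusCan <- corpusCan$smiles_canonical[corpusCan$valid]
  list(uniqueness = length(uniq) / length(can),
       novelty = mean(!(uniq %in% corpusCan)),
       nValid = length(can))
}

.pairwiseTanimoto <- function(F1, F2) {
  inter <- F1 %*% t(F2)
  n1 <- rowSums(F1)
  n2 <- rowSums(F2)
  uni <- outer(n1, n2, `+`) - inter
  sim <- inter / pmax(uni, 1e-12)
  sim[uni == 0] <- 1
  sim
}

#' Tanimoto diversity of a molecule set
#'
#' Internal diversity is 1 minus the mean pairwise ECFP Tanimoto similarity
#' within the sample; external diversity (when a reference set is given) is
#' 1 minus the mean similarity of each sample molecule to its nearest
#' reference neighbor.
#'
#' @param sample character vector of SMILES (>= 2 valid).
#' @param reference optional reference SMILES (training set).
#' @param radius fingerprint radius (2 = ECFP4).
#' @param nbits fingerprint length.
#' @return diversity value in [0, 1].
#' @export
diversity <- function(sample, reference = NULL, radius = 2, nbits = 2048) {
  rec <- canonicalizeSmiles(sample)
  can <- rec$smiles_canonical[rec$valid]  # duplicates kept: they lower diversity
  if (length(can) < 2 && is.null(reference)) stop("need >= 2 valid molecules")
  desc <- if (radius == 2) "ECFP4" else "ECFP6"
  Fs <- .fpForSmiles(can, desc, nbits)
  if (is.null(reference)) {
    sim <- .pairwiseTanimoto(Fs, Fs)
    n <- nrow(sim)
    return(1 - mean(sim[upper.tri(sim)]))
  }
  rrec <- canonicalizeSmiles(reference)
  rcan <- unique(rrec$smiles_canonical[rrec$valid])
  if (!length(rcan)) stop("no valid reference molecules")
  Fr <- .fpForSmiles(rcan, desc, nbits)
  sim <- .pairwiseTanimoto(Fs, Fr)
  1 - mean(apply(sim, 1L, max))
}

# physicochemical descriptor table used by the KLD score
.kldDescriptors <- function(smiles) {
  rec <- computeDescriptors(canonicalizeSmiles(smiles))
  graphs <- molGraphs(rec$smiles_canonical[rec$valid])
  rows <- lapply(graphs, function(g) {
    if (is.null(g)) return(NULL)
    cs <- .countSubstructures(g)
    nb <- nrow(g$bonds)
    data.frame(ringCount = cs$nRings, aromRings = cs$nAromRings,
               fracSp3 = cs$fracSp3, heavyAtoms = cs$nHeavy,
               complexity = nb * log2(nb + 1) +
                 sum(g$elements != "C" & g$elements != "H"))
  })
  keep <- !vapply(rows, is.null, logical(1))
  cbind(rec[rec$valid, c("mw", "logp", "sas")][keep, , drop = FALSE],
        do.call(rbind, rows[keep]))
}

.klDivergence <- function(x, ref, bins = 50, discrete = FALSE) {
  eps <- 1e-10
  if (discrete) {
    lev <- sort(unique(c(x, ref)))
    p <- (tabulate(match(x, lev), length(lev)) + eps)
    q <- (tabulate(match(ref, lev), length(lev)) + eps)
  } else {
    lo <- stats::quantile(ref, 0.001, names = FALSE)
    hi <- stats::quantile(ref, 0.999, names = FALSE)
    if (hi <= lo) return(NA_real_)
    brk <- seq(lo, hi, length.out = bins + 1L)
    cut_ <- function(v) {
      v <- pmin(pmax(v, lo), hi)
      tabulate(findInterval(v, brk, rightmost.closed = TRUE), bins) + eps
    }
    p <- cut_(x)
    q <- cut_(ref)
  }
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

#' KL-divergence distribution-matching score
#'
#' For each physicochemical descriptor (MW, logP, SAS, ring count, aromatic
#' ring count, fraction of sp3 carbons, heavy-atom count, graph complexity),
#' the Kullback-Leibler divergence KL(sample || reference) is estimated
#' (50-bin histograms over the reference's 0.1-99.9 percentile span for
#' continuous descriptors, categorical otherwise) and aggregated as the mean
#' of exp(-KL): 1 means matching distributions. Degenerate descriptors
#' (zero variance in the reference) are skipped with a flag. The direction of
#' the divergence is fixed (sample against reference); the score is not
#' symmetric by design.
#'
#' @param sample,reference character vectors of SMILES (>= \code{minN} valid
#'   each).
#' @param bins histogram bins for continuous descriptors.
#' @param aggregate \code{"exp"} (mean of exp(-KL), default) or
#'   \code{"mean_kl"} (plain mean KL, lower is better).
#' @param minN minimum valid molecules per set.
#' @return list with \code{score}, per-descriptor \code{kl}, and
#'   \code{skipped} descriptor names.
#' @export
kldScore <- function(sample, reference, bins = 50, aggregate = c("exp", "mean_kl"),
                     minN = 100L) {
  aggregate <- match.arg(aggregate)
  ds <- .kldDescriptors(sample)
  dr <- .kldDescriptors(reference)
  if (nrow(ds) < minN || nrow(dr) < minN)
    stop("need at least ", minN, " valid molecules in each set")
  discrete <- c(ringCount = TRUE, aromRings = TRUE, heavyAtoms = TRUE,
                mw = FALSE, logp = FALSE, sas = FALSE, fracSp3 = FALSE,
                complexity = FALSE)
  kl <- numeric(0)
  skipped <- character(0)
  for (d in names(ds)) {
    if (stats::var(dr[[d]]) == 0 && !discrete[[d]]) {
      skipped <- c(skipped, d)
      next
    }
    v <- .klDivergence(ds[[d]], dr[[d]], bins, discrete[[d]])
    if (is.na(v)) skipped <- c(skipped, d) else kl[d] <- v
  }
  score <- if (aggregate == "exp") mean(exp(-kl)) else mean(kl)
  list(score = score, kl = kl, skipped = skipped)
}

#' Property-shift report between two generated samples
#'
#' Compares predicted pIC50 and synthetic accessibility of an unbiased and a
#' biased (conditioned) sample: per-sample mean and standard deviation plus
#' the difference of means, the summary behind before/after conditioning
#' histograms.
#'
#' @param unbiased,biased character vectors of raw SMILES.
#' @param predictor a trained \linkS4class{Pic50Predictor}.
#' @return data.frame with one row per (property, sample) and an attached
#'   \code{shift} attribute (biased minus unbiased mean per property).
#' @export
propertyShiftReport <- function(unbiased, biased, predictor) {
  scoreSet <- function(smiles, label) {
    rec <- canonicalizeSmiles(smiles)
    can <- rec$smiles_canonical[rec$valid]
    p <- predictPic50(predictor, can)$pic50
    s <- syntheticAccessibility(can)
    data.frame(sample = label, n = length(smiles), nValid = length(can),
               property = c("pic50", "sas"),
               mean = c(mean(p, na.rm = TRUE), mean(s, na.rm = TRUE)),
               sd = c(stats::sd(p), stats::sd(s)),
               stringsAsFactors = FALSE)
  }
  a <- scoreSet(unbiased, "unbiased")
  b <- scoreSet(biased, "biased")
  out <- rbind(a, b)
  shift <- c(pic50 = b$mean[b$property == "pic50"] -
               a$mean[a$property == "pic50"],
             sas = b$mean[b$property == "sas"] - a$mean[a$property == "sas"])
  attr(out, "shift") <- shift
  out
}

#' Full generation report
#'
#' Validity, uniqueness, novelty, internal/external diversity, KLD score and
#' property summaries of a generated sample against a training corpus. The
#' Frechet-ChemNet field is reported as NA: that metric requires an external
#' trained reference network and is out of scope.
#'
#' @param sample character vector of raw SMILES.
#' @param corpus training corpus.
#' @param predictor optional \linkS4class{Pic50Predictor} for property
#'   summaries.
#' @param nbits fingerprint length for diversity.
#' @return named list (a GenerationReport).
#' @export
generationReport <- function(sample, corpus, predictor = NULL, nbits = 2048) {
  un <- uniquenessNovelty(sample, corpus)
  rep_ <- list(n = length(sample),
               validity = validity(sample),
               uniqueness = un$uniqueness,
               novelty = un$novelty,
               internal_diversity = tryCatch(diversity(sample, nbits = nbits),
                                             error = function(e) NA_real_),
               external_diversity = tryCatch(
                 diversity(sample, reference = corpus, nbits = nbits),
                 error = function(e) NA_real_),
               kld_score = tryCatch(kldScore(sample, corpus)$score,
                                    error = function(e) NA_real_),
               fcd = NA_real_)
  if (!is.null(predictor)) {
    rec <- canonicalizeSmiles(sample)
    can <- rec$smiles_canonical[rec$valid]
    if (length(can)) {
      p <- predictPic50(predictor, can)$pic50
      s <- syntheticAccessibility(can)
      rep_$pic50_mean_sd <- c(mean = mean(p, na.rm = TRUE), sd = stats::sd(p))
      rep_$sas_mean_sd <- c(mean = mean(s, na.rm = TRUE), sd = stats::sd(s))
    }
  }
  rep_
}
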