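# Chemistry core: canonicalization contract, molecular graphs, descriptors,
# fingerprints and file I/O. Structure handling is delegated to Open Babel
# (through ChemmineOB/ChemmineR); on top of it sits a strict SMILES syntax and
# valence gate, because Open Babel silently repairs several classes of
# malformed input (unbalanced branches, hypervalent atoms, empty branches)
# that a validity oracle must reject.

.maxValence <- c(B = 3, C = 4, N = 5, O = 2, P = 5, S = 6,
                 F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = 6, H = 1)

.atomTokenPattern <- function() "^\\[|^(Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s)$"

.isAtomToken <- function(tok) grepl(.atomTokenPattern(), tok)

.isRingToken <- function(tok) grepl("^[0-9]$|^%[0-9][0-9]$", tok)

.bracketInfo <- function(tok) {
  # element, aromatic flag, explicit H count and |charge| of a [...] token
  body <- sub("^\\[", "", sub("\\]$", "", tok))
  m <- regexpr("^([A-Z][a-z]?|[a-z]{1,2})", body)
  if (m < 0) return(NULL)
  elem <- regmatches(body, m)
  rest <- substr(body, attr(m, "match.length") + 1L, nchar(body))
  arom <- elem %in% c("b", "c", "n", "o", "p", "s", "se")
  elem <- paste0(toupper(substr(elem, 1, 1)), substr(elem, 2, nchar(elem)))
  nH <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]?", rest))
  if (length(hm)) nH <- if (nchar(hm) == 1L) 1L else as.integer(substr(hm, 2, 2))
  charge <- sum(gregexpr("[+-]", rest)[[1]] > 0)
  list(elem = elem, aromatic = arom, nH = nH, charge = charge)
}

#' Check SMILES syntax and valence without external toolkits
#'
#' Token-level structural validation: every token must be known to the
#' vocabulary; branches must balance and be non-empty; ring-bond digits must
#' pair exactly; bond symbols must connect two atoms; and no atom may exceed
#' the standard maximum valence of its element (allowing common hypervalent
#' nitrogen/sulfur/phosphorus forms). Aromatic bonds count as order one for
#' the valence tally.
#'
#' @param smiles single SMILES string.
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @return logical; \code{TRUE} if the string passes all structural checks.
#' @export
smilesSyntaxOk <- function(smiles, vocab = defaultVocabulary()) {
  if (!nzchar(smiles) || grepl("\\s", smiles)) return(FALSE)
  toks <- tokenizeSmiles(smiles, vocab)
  if (vocab@specials[["UNK"]] %in% toks) return(FALSE)
  if (any(toks %in% vocab@specials)) return(FALSE)

  nAtoms <- 0L
  valence <- numeric(0)     # accumulated bond order per atom
  maxv <- numeric(0)        # per-atom cap
  aromAtom <- logical(0)
  prevAtom <- NA_integer_   # atom awaiting the next bond
  stack <- integer(0)
  pendingBond <- NA_real_   # order set by an explicit bond symbol
  open_rings <- list()      # digit -> list(atom, order)
  lastWasBond <- FALSE

  addBond <- function(a, b, order) {
    valence[a] <<- valence[a] + order
    valence[b] <<- valence[b] + order
  }

  for (k in seq_along(toks)) {
    tok <- toks[k]
    if (.isAtomToken(tok)) {
      nAtoms <- nAtoms + 1L
      if (grepl("^\\[", tok)) {
        bi <- .bracketInfo(tok)
        if (is.null(bi) || !(bi$elem %in% names(.maxValence))) return(FALSE)
        cap <- .maxValence[[bi$elem]] + bi$charge
        valence <- c(valence, bi$nH)
        aromAtom <- c(aromAtom, bi$aromatic)
      } else {
        arom <- tok %in% c("b", "c", "n", "o", "p", "s")
        elem <- paste0(toupper(substr(tok, 1, 1)), substr(tok, 2, nchar(tok)))
        cap <- .maxValence[[elem]]
        valence <- c(valence, 0)
        aromAtom <- c(aromAtom, arom)
      }
      maxv <- c(maxv, cap)
      if (!is.na(prevAtom)) {
        order <- if (!is.na(pendingBond)) pendingBond
                 else if (aromAtom[prevAtom] && aromAtom[nAtoms]) 1 else 1
        addBond(prevAtom, nAtoms, order)
      }
      prevAtom <- nAtoms
      pendingBond <- NA_real_
      lastWasBond <- FALSE
    } else if (tok == "(") {
      if (is.na(prevAtom) || lastWasBond) return(FALSE)
      if (k > 1L && toks[k - 1L] == "(") return(FALSE)  # branch within branch head
      stack <- c(stack, prevAtom)
    } else if (tok == ")") {
      if (!length(stack) || lastWasBond || !is.na(pendingBond)) return(FALSE)
      if (k > 1L && toks[k - 1L] == "(") return(FALSE)  # empty branch
      prevAtom <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok %in% c("-", "=", "#", ":", "/", "\\")) {
      if (is.na(prevAtom) || lastWasBond) return(FALSE)
      pendingBond <- switch(tok, "-" = 1, "=" = 2, "#" = 3, ":" = 1,
                            "/" = 1, "\\" = 1)
      lastWasBond <- TRUE
    } else if (.isRingToken(tok)) {
      if (is.na(prevAtom)) return(FALSE)
      if (!is.null(open_rings[[tok]])) {
        op <- open_rings[[tok]]
        if (op$atom == prevAtom) return(FALSE)  # self ring bond
        order <- if (!is.na(pendingBond)) pendingBond
                 else if (!is.na(op$order)) op$order else 1
        addBond(op$atom, prevAtom, order)
        open_rings[[tok]] <- NULL
      } else {
        open_rings[[tok]] <- list(atom = prevAtom, order = pendingBond)
      }
      pendingBond <- NA_real_
      lastWasBond <- FALSE
    } else if (tok == ".") {
      if (is.na(prevAtom) || lastWasBond || length(stack)) return(FALSE)
      prevAtom <- NA_integer_
    } else if (tok %in% c("@", "@@", "+")) {
      return(FALSE)  # only legal inside bracket atoms
    } else {
      return(FALSE)
    }
  }
  if (length(stack) || lastWasBond || length(open_rings) || nAtoms == 0L)
    return(FALSE)
  # aromatic atoms tolerate a half-bond of slack from kekulization
  all(valence <= maxv + ifelse(aromAtom, 0.5, 0))
}

.obConvert <- function(from, to, lines) {
  # batch Open Babel conversion keyed by title, so failed molecules drop out
  # without breaking the alignment of the survivors
  input <- paste0(paste(lines, paste0("m", seq_along(lines))), "\n",
                  collapse = "")
  out <- tryCatch(ChemmineOB::convertFormat(from, to, input),
                  error = function(e) "")
  out
}

.obCanonical <- function(smiles) {
  # returns named character vector indexed by position; NA where OB failed
  res <- rep(NA_character_, length(smiles))
  if (!length(smiles)) return(res)
  out <- .obConvert("SMI", "CAN", smiles)
  if (!nzchar(out)) return(res)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) == 2L) {
      i <- as.integer(sub("^m", "", p[2]))
      if (!is.na(i) && i >= 1L && i <= length(res)) res[i] <- p[1]
    }
  }
  res
}

#' Canonicalize SMILES strings
#'
#' Each string passes the structural gate (\code{\link{smilesSyntaxOk}}) and is
#' then canonicalized by Open Babel. The result is a molecule-record table:
#' invalid strings keep their raw form with \code{valid = FALSE}.
#' Canonicalization is idempotent on its own output, and two spellings of the
#' same molecule share one canonical form.
#'
#' @param smiles character vector of non-empty SMILES strings.
#' @param isomeric keep stereochemistry in the canonical form (default) or
#'   strip it first.
#' @param vocab a \linkS4class{TokenVocabulary} for the syntax gate.
#' @return \code{data.frame} with columns \code{smiles_raw},
#'   \code{smiles_canonical} (NA when invalid) and \code{valid}.
#' @examples
#' canonicalizeSmiles(c("OCC", "CCO", "C("))
#' @export
canonicalizeSmiles <- function(smiles, isomeric = TRUE,
                               vocab = defaultVocabulary()) {
  if (!length(smiles)) stop("no SMILES given")
  if (any(!nzchar(smiles))) stop("empty SMILES string")
  ok <- vapply(smiles, smilesSyntaxOk, logical(1), vocab = vocab,
               USE.NAMES = FALSE)
  query <- smiles
  if (!isomeric)
    query <- gsub("@|/|\\\\", "", query)  # bracket Hs survive; OB renormalizes
  canon <- rep(NA_character_, length(smiles))
  if (any(ok)) canon[ok] <- .obCanonical(query[ok])
  valid <- ok & !is.na(canon)
  data.frame(smiles_raw = smiles, smiles_canonical = canon,
             valid = valid, stringsAsFactors = FALSE)
}

# ---- molecular graphs -------------------------------------------------------

#' Build molecular graphs from canonical SMILES
#'
#' Converts each SMILES to an MDL SDF block (atom order follows the SMILES
#' atom order) and extracts elements, the bond list with kekulized orders, and
#' aromaticity flags taken from the lowercase/bracket aromatic tokens of the
#' SMILES itself.
#'
#' @param smiles character vector of valid SMILES.
#' @param vocab vocabulary used to locate atom tokens.
#' @return list of graphs; each is a list with \code{elements} (character),
#'   \code{bonds} (matrix with columns a1, a2, order), \code{aromatic}
#'   (logical per atom), \code{tokens}, \code{atomTokenPos} (token index of
#'   each atom). Entries are \code{NULL} where conversion failed.
#' @export
molGraphs <- function(smiles, vocab = defaultVocabulary()) {
  res <- vector("list", length(smiles))
  if (!length(smiles)) return(res)
  sdftext <- .obConvert("SMI", "SDF", smiles)
  if (!nzchar(sdftext)) return(res)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdftext, tf)
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                     error = function(e) NULL)
  if (is.null(sdfset)) return(res)
  ids <- ChemmineR::sdfid(sdfset)
  for (k in seq_along(sdfset)) {
    i <- suppressWarnings(as.integer(sub("^m", "", ids[k])))
    if (is.na(i) || i < 1L || i > length(res)) next
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
      matrix(as.numeric(bb[, 1:3, drop = FALSE]), ncol = 3,
             dimnames = list(NULL, c("a1", "a2", "order")))
    } else matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("a1", "a2", "order")))
    toks <- tokenizeSmiles(smiles[i], vocab)
    atomPos <- which(.isAtomToken(toks))
    arom <- rep(FALSE, length(elements))
    if (length(atomPos) == length(elements)) {
      atoks <- toks[atomPos]
      arom <- grepl("^[bcnops]", atoks) |
        grepl("^\\[(b|c|n|o|p|s|se)", atoks)
    } else {
      atomPos <- rep(NA_integer_, length(elements))
    }
    res[[i]] <- list(elements = elements, bonds = bonds, aromatic = arom,
                     tokens = toks, atomTokenPos = atomPos)
  }
  res
}

.graphAdjacency <- function(g) {
  n <- length(g$elements)
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      a <- g$bonds[r, 1]; b <- g$bonds[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

.implicitH <- function(g) {
  # implicit hydrogen estimate from standard valences and explicit bond orders
  n <- length(g$elements)
  vs <- numeric(n)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      o <- g$bonds[r, 3]
      vs[g$bonds[r, 1]] <- vs[g$bonds[r, 1]] + o
      vs[g$bonds[r, 2]] <- vs[g$bonds[r, 2]] + o
    }
  }
  std <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
           F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = 2, H = 0)
  cap <- std[g$elements]
  cap[is.na(cap)] <- 0
  pmax(0, round(cap - vs))
}

.countSubstructures <- function(g) {
  # substructure counts used by the affinity oracle and the KLD descriptors
  elems <- g$elements
  adj <- .graphAdjacency(g)
  nN <- sum(elems == "N")
  nHal <- sum(elems %in% c("F", "Cl", "Br", "I"))
  nHeavy <- sum(elems != "H")
  # amide: C with a double-bonded O and a single-bonded N
  nAmide <- 0L
  if (nrow(g$bonds)) {
    for (a in which(elems == "C")) {
      nb <- adj[[a]]
      if (!length(nb)) next
      hasDoubleO <- FALSE; hasSingleN <- FALSE
      for (b in nb) {
        row <- which((g$bonds[, 1] == a & g$bonds[, 2] == b) |
                     (g$bonds[, 2] == a & g$bonds[, 1] == b))[1]
        o <- g$bonds[row, 3]
        if (elems[b] == "O" && o == 2) hasDoubleO <- TRUE
        if (elems[b] == "N" && o == 1) hasSingleN <- TRUE
      }
      if (hasDoubleO && hasSingleN) nAmide <- nAmide + 1L
    }
  }
  nRings <- nrow(g$bonds) - nHeavy + .nComponents(g)
  aromIdx <- which(g$aromatic)
  nAromBonds <- if (nrow(g$bonds))
    sum(g$bonds[, 1] %in% aromIdx & g$bonds[, 2] %in% aromIdx) else 0L
  nAromRings <- max(0L, nAromBonds - length(aromIdx) +
                      .nComponentsSub(g, aromIdx))
  degree <- lengths(adj)
  sp3C <- sum(elems == "C" & !g$aromatic &
                vapply(seq_along(elems), function(a) {
                  if (elems[a] != "C") return(FALSE)
                  rows <- which(g$bonds[, 1] == a | g$bonds[, 2] == a)
                  all(g$bonds[rows, 3] == 1)
                }, logical(1)))
  list(nN = nN, nHal = nHal, nAmide = nAmide, nHeavy = nHeavy,
       nRings = max(0L, nRings), nAromRings = nAromRings,
       fracSp3 = if (sum(elems == "C")) sp3C / sum(elems == "C") else 0,
       degree = degree)
}

.nComponents <- function(g) .nComponentsSub(g, seq_along(g$elements))

.nComponentsSub <- function(g, keep) {
  if (!length(keep)) return(0L)
  n <- length(g$elements)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(g$bonds)) {
    inKeep <- logical(n); inKeep[keep] <- TRUE
    for (r in seq_len(nrow(g$bonds))) {
      a <- g$bonds[r, 1]; b <- g$bonds[r, 2]
      if (inKeep[a] && inKeep[b]) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  length(unique(vapply(keep, find, numeric(1))))
}

# ---- descriptors ------------------------------------------------------------

#' Compute molecular descriptors
#'
#' Adds molecular weight (g/mol), Crippen logP and the synthetic accessibility
#' score (1 = easy to 10 = practically impossible) to a molecule-record table.
#' MW and logP come from Open Babel's descriptor engine; the SA score is
#' computed by \code{\link{syntheticAccessibility}}.
#'
#' @param records data.frame from \code{\link{canonicalizeSmiles}} (or any
#'   data.frame with \code{smiles_canonical} and \code{valid} columns).
#' @param sas also compute the synthetic accessibility score (default TRUE;
#'   it is the costliest descriptor).
#' @return the table with numeric columns \code{mw}, \code{logp}, \code{sas}
#'   (NA for invalid rows).
#' @export
computeDescriptors <- function(records, sas = TRUE) {
  if (!all(c("smiles_canonical", "valid") %in% names(records)))
    stop("records must come from canonicalizeSmiles()")
  n <- nrow(records)
  records$mw <- NA_real_
  records$logp <- NA_real_
  records$sas <- NA_real_
  vidx <- which(records$valid)
  if (!length(vidx)) return(records)
  smis <- records$smiles_canonical[vidx]
  sdftext <- .obConvert("SMI", "SDF", smis)
  if (nzchar(sdftext)) {
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf))
    writeLines(sdftext, tf)
    sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                     error = function(e) NULL)
    if (!is.null(sdfset)) {
      props <- tryCatch(ChemmineR::propOB(sdfset), error = function(e) NULL)
      if (!is.null(props)) {
        ids <- suppressWarnings(as.integer(sub("^m", "",
                                               ChemmineR::sdfid(sdfset))))
        okid <- !is.na(ids) & ids >= 1L & ids <= length(vidx)
        records$mw[vidx[ids[okid]]] <- props$MW[okid]
        records$logp[vidx[ids[okid]]] <- props$logP[okid]
      }
    }
  }
  if (sas) records$sas[vidx] <- syntheticAccessibility(smis)
  records
}

#' Filter a corpus to the drug-like training window
#'
#' Retains valid molecules with molecular weight in [200, 600] g/mol and logP
#' in [-2, 6] (closed intervals). Records must already carry descriptors; if
#' not, they are computed.
#'
#' @param records molecule-record data.frame.
#' @return the retained subset (possibly empty), row names reset.
#' @export
filterTrainingSet <- function(records) {
  if (!("mw" %in% names(records))) records <- computeDescriptors(records)
  keep <- records$valid &
    !is.na(records$mw) & records$mw >= 200 & records$mw <= 600 &
    !is.na(records$logp) & records$logp >= -2 & records$logp <= 6
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- fingerprints -----------------------------------------------------------

#' Extended-connectivity fingerprint of a molecule
#'
#' Circular Morgan-style fingerprint: atom neighborhoods up to \code{radius}
#' bonds are hashed to bit positions. Radius 2 corresponds to ECFP4, radius 3
#' to ECFP6. The native 4096-bit vector is folded by OR to \code{nbits}.
#'
#' @param smiles single valid SMILES string.
#' @param radius neighborhood radius (1, 2 or 3).
#' @param nbits folded fingerprint length (must divide 4096).
#' @return integer 0/1 vector of length \code{nbits} with attributes
#'   \code{radius} and \code{nbits}.
#' @export
ecfp <- function(smiles, radius = 2, nbits = 2048) {
  if (length(smiles) != 1L || !nzchar(smiles)) stop("one non-empty SMILES required")
  if (!radius %in% 1:3) stop("radius must be 1, 2 or 3")
  if (4096 %% nbits != 0) stop("nbits must divide 4096")
  fpname <- c("ECFP2", "ECFP4", "ECFP6")[radius]
  mol <- tryCatch(ChemmineOB::forEachMol("SMILES", smiles, identity),
                  error = function(e) NULL)
  if (is.null(mol)) stop("invalid molecule: ", smiles)
  bits <- tryCatch(ChemmineOB::fingerprint_OB(mol, fpname),
                   error = function(e) NULL)
  if (is.null(bits) || !sum(bits)) {
    # OB returns an empty vector for an unparseable or empty molecule
    if (is.null(bits)) stop("fingerprint failed for: ", smiles)
  }
  folded <- as.integer(colSums(matrix(bits, ncol = nbits, byrow = TRUE)) > 0)
  structure(folded, radius = radius, nbits = nbits)
}

#' Tanimoto similarity of two bit vectors
#'
#' @param a,b equal-length binary vectors.
#' @return Jaccard index of the on-bit sets, in [0, 1]; defined as 1 when both
#'   vectors are all-zero.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# ---- file I/O ---------------------------------------------------------------

#' Read a SMILES file
#'
#' Accepts SMI format (one SMILES per line, optional whitespace-separated
#' name) or a CSV whose first column (or a column named \code{smiles}) holds
#' the SMILES. CRLF and LF line endings both parse. Records are canonicalized.
#'
#' @param path file path.
#' @param canonicalize run \code{\link{canonicalizeSmiles}} (default TRUE).
#' @return molecule-record data.frame (with \code{name} column when present).
#' @export
readSmilesFile <- function(path, canonicalize = TRUE) {
  if (!file.exists(path)) stop("cannot read ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no SMILES in ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE) || grepl(",", lines[1])) {
    df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
    col <- if ("smiles" %in% names(df)) "smiles" else names(df)[1]
    smis <- as.character(df[[col]])
    names_ <- rep(NA_character_, length(smis))
  } else {
    parts <- strsplit(trimws(lines), "\\s+")
    smis <- vapply(parts, `[`, character(1), 1)
    names_ <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                     character(1))
  }
  if (canonicalize) {
    rec <- canonicalizeSmiles(smis)
  } else {
    rec <- data.frame(smiles_raw = smis, smiles_canonical = smis,
                      valid = NA, stringsAsFactors = FALSE)
  }
  rec$name <- names_
  rec
}

#' Write molecule records
#'
#' \code{writeSmilesFile} writes SMI (canonical SMILES, optional name column);
#' \code{writeTable} writes a CSV with a header row. Both round-trip through
#' \code{\link{readSmilesFile}} / \code{read.csv}.
#'
#' @param records molecule-record data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSmilesFile <- function(records, path) {
  smi <- records$smiles_canonical
  smi[is.na(smi)] <- records$smiles_raw[is.na(smi)]
  lines <- if (!is.null(records$name) && any(!is.na(records$name)))
    paste(smi, ifelse(is.na(records$name), "", records$name)) else smi
  writeLines(trimws(lines), path)
  invisible(path)
}

#' @rdname writeSmilesFile
#' @export
writeTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
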