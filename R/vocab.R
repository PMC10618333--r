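#' @import methods
NULL

#' Token vocabulary for SMILES sequence models
#'
#' A bijective mapping between SMILES tokens and integer codes. Multi-character
#' chemistry tokens (\code{"Cl"}, \code{"Br"}, \code{"@@"}, bracket atoms such
#' as \code{"[nH]"}, two-digit ring closures \code{"\%nn"}) are atomic entries,
#' so the greedy longest-match tokenizer never splits them. Four special tokens
#' are reserved: \code{<PAD>} (always code 0), \code{<GO>}, \code{<EOS>} and
#' \code{<UNK>}. Codes are 0-based so that padding and masking conventions
#' match the sequence-model literature; add 1 when indexing R matrices.
#'
#' @slot tokens character vector of all tokens, in code order (code 0 first).
#' @slot specials named character vector with entries \code{PAD}, \code{GO},
#'   \code{EOS}, \code{UNK}.
#' @exportClass TokenVocabulary
setClass("TokenVocabulary",
  representation(tokens = "character", specials = "character"))

setValidity("TokenVocabulary", function(object) {
  msgs <- character()
  if (anyDuplicated(object@tokens))
    msgs <- c(msgs, "tokens must be unique (bijective mapping)")
  need <- c("PAD", "GO", "EOS", "UNK")
  if (!all(need %in% names(object@specials)))
    msgs <- c(msgs, "specials must name PAD, GO, EOS, UNK")
  else {
    if (!all(object@specials %in% object@tokens))
      msgs <- c(msgs, "special tokens must be vocabulary entries")
    if (object@tokens[1L] != object@specials[["PAD"]])
      msgs <- c(msgs, "PAD must have code 0 (first token)")
  }
  if (length(msgs)) msgs else TRUE
})

# core multi-character tokens that must never be split
.MULTI_TOKENS <- c("Cl", "Br", "@@")

#' Construct the default SMILES vocabulary
#'
#' Covers the organic subset (B, C, N, O, P, S, F, Cl, Br, I and their aromatic
#' forms), common bracket atoms including chiral and charged variants, ring
#' closure digits 1-9 plus two-digit \code{\%nn} closures, bond symbols and the
#' stereo markers \code{@}, \code{@@}, \code{/} and \code{\\}. Additional
#' bracket-atom tokens found in a corpus can be appended with
#' \code{extra}.
#'
#' @param extra optional character vector of additional tokens.
#' @return a \linkS4class{TokenVocabulary}.
#' @examples
#' v <- defaultVocabulary()
#' tokenizeSmiles("ClCBr", v)
#' @export
defaultVocabulary <- function(extra = character()) {
  specials <- c(PAD = "<PAD>", GO = "<GO>", EOS = "<EOS>", UNK = "<UNK>")
  organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
               "b", "c", "n", "o", "p", "s")
  bracket <- c("[nH]", "[NH]", "[N+]", "[NH2+]", "[NH3+]", "[N-]", "[n+]",
               "[O-]", "[o+]", "[S-]", "[s+]", "[C@]", "[C@@]", "[C@H]",
               "[C@@H]", "[CH]", "[C-]", "[Si]", "[Se]", "[se]", "[P+]",
               "[B-]", "[H]")
  rings <- c(as.character(1:9), "0", paste0("%", 10:25))
  bonds <- c("-", "=", "#", ":", "/", "\\")
  structure_ <- c("(", ")", ".", "@", "@@", "+")
  toks <- unique(c(unname(specials), organic, bracket, rings, bonds,
                   structure_, extra))
  new("TokenVocabulary", tokens = toks, specials = specials)
}

#' Build a vocabulary from a corpus
#'
#' Starts from \code{\link{defaultVocabulary}} and appends any bracket-atom
#' token present in the corpus but missing from the default list, so that every
#' corpus string tokenizes without \code{<UNK>}.
#'
#' @param smiles character vector of SMILES strings.
#' @return a \linkS4class{TokenVocabulary}.
#' @export
vocabularyFromCorpus <- function(smiles) {
  brackets <- unlist(regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles)))
  defaultVocabulary(extra = sort(unique(brackets)))
}

#' Number of tokens in a vocabulary
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @return integer vocabulary size.
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' Tokens of a vocabulary, in code order
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @return character vector.
#' @export
vocabTokens <- function(vocab) vocab@tokens

#' Integer code of tokens (0-based; PAD is 0)
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @param tokens character vector of tokens.
#' @return integer codes; unknown tokens get the \code{<UNK>} code.
#' @export
tokenIndex <- function(vocab, tokens) {
  idx <- match(tokens, vocab@tokens)
  idx[is.na(idx)] <- match(vocab@specials[["UNK"]], vocab@tokens)
  idx - 1L
}

setMethod("show", "TokenVocabulary", function(object) {
  cat("TokenVocabulary with", length(object@tokens), "tokens\n")
  cat(" specials:", paste(object@specials, collapse = " "), "\n")
})

#' Tokenize a SMILES string
#'
#' Greedy longest-match segmentation over the vocabulary token list. Bracket
#' atoms (\code{[...]}) are always emitted as single tokens; if a bracket atom
#' is not in the vocabulary it becomes \code{<UNK>}. Any other character with
#' no vocabulary entry also maps to \code{<UNK>}. Concatenating the returned
#' tokens (with \code{<UNK>} spans excluded) reproduces the input.
#'
#' @param smiles a single SMILES string (non-empty).
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @return character vector of tokens.
#' @examples
#' tokenizeSmiles("C/C=C\\Cl", defaultVocabulary())
#' @export
tokenizeSmiles <- function(smiles, vocab = defaultVocabulary()) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a single non-empty string")
  toks <- character(0)
  i <- 1L
  n <- nchar(smiles)
  unk <- vocab@specials[["UNK"]]
  has2 <- vocab@tokens[nchar(vocab@tokens) == 2L & !grepl("^\\[", vocab@tokens)]
  while (i <= n) {
    ch <- substr(smiles, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(smiles, i, n), fixed = TRUE)
      if (j < 0) { toks <- c(toks, unk); i <- i + 1L; next }
      tok <- substr(smiles, i, i + j - 1L)
      toks <- c(toks, if (tok %in% vocab@tokens) tok else unk)
      i <- i + j
    } else if (ch == "%") {
      tok <- substr(smiles, i, i + 2L)
      toks <- c(toks, if (tok %in% vocab@tokens) tok else unk)
      i <- i + 3L
    } else {
      two <- substr(smiles, i, i + 1L)
      if (i < n && two %in% has2) {
        toks <- c(toks, two)
        i <- i + 2L
      } else {
        toks <- c(toks, if (ch %in% vocab@tokens) ch else unk)
        i <- i + 1L
      }
    }
  }
  toks
}

#' Encode a token sequence with GO/EOS framing and PAD right-padding
#'
#' @param tokens character vector of tokens (may be empty).
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @param maxLen maximum number of payload tokens; output length is
#'   \code{maxLen + 2}.
#' @return integer vector of 0-based codes:
#'   \code{GO, tokens..., EOS, PAD...}.
#' @export
padEncode <- function(tokens, vocab, maxLen) {
  if (length(tokens) > maxLen)
    stop("sequence of ", length(tokens), " tokens exceeds maxLen = ", maxLen)
  sp <- vocab@specials
  codes <- c(tokenIndex(vocab, sp[["GO"]]),
             tokenIndex(vocab, tokens),
             tokenIndex(vocab, sp[["EOS"]]),
             rep(tokenIndex(vocab, sp[["PAD"]]), maxLen - length(tokens)))
  as.integer(codes)
}

#' Decode an encoded sequence back to tokens
#'
#' Inverts \code{\link{padEncode}}: strips the leading GO, stops at the first
#' EOS (or PAD) and maps codes back to tokens.
#'
#' @param codes integer vector of 0-based codes.
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @return character vector of payload tokens.
#' @export
padDecode <- function(codes, vocab) {
  toks <- vocab@tokens[codes + 1L]
  sp <- vocab@specials
  if (length(toks) && toks[1L] == sp[["GO"]]) toks <- toks[-1L]
  stop_at <- which(toks %in% c(sp[["EOS"]], sp[["PAD"]]))
  if (length(stop_at)) toks <- toks[seq_len(stop_at[1L] - 1L)]
  toks
}

#' Reassemble tokens into a SMILES string
#' @param tokens character vector of tokens (specials are dropped).
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @return single string.
#' @export
detokenize <- function(tokens, vocab = defaultVocabulary()) {
  paste(tokens[!(tokens %in% vocab@specials)], collapse = "")
}
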