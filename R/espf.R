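# Frequency-based substructure featurization of SMILES strings: a byte-pair
# encoding over SMILES token sequences with greedy longest-match encoding.
# Starting from single characters (two-letter halogens Cl/Br kept atomic), the
# most frequent adjacent token pair with count >= min_freq is merged, until the
# vocabulary reaches max_size tokens or no pair qualifies. Ties are broken by
# the lexicographically smallest merged string, so fitting is deterministic.

espf_tokenize <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(character(0))
  regmatches(smiles, gregexpr("Cl|Br|.", smiles))[[1]]
}

#' Fit a frequent-substructure vocabulary on a SMILES corpus
#'
#' @param smiles_list character vector of SMILES strings (the fitting corpus).
#' @param min_freq minimum corpus count for a pair to be merged.
#' @param max_size cap on the total number of vocabulary tokens. All unigrams
#'   are always retained; the cap limits how many merged tokens are added.
#' @return an object of class `espf_vocab` with fields `tokens`, `min_freq`,
#'   `max_size`.
#' @examples
#' v <- espf_fit(c("CCO", "CCO"), min_freq = 2, max_size = 10)
#' "CC" %in% v$tokens
#' @export
espf_fit <- function(smiles_list, min_freq = 2L, max_size = 2048L) {
  smiles_list <- smiles_list[!is.na(smiles_list) & nzchar(smiles_list)]
  if (!length(smiles_list)) stop("espf_fit: empty SMILES corpus")
  seqs <- lapply(smiles_list, espf_tokenize)
  unigrams <- unique(unlist(seqs))
  vocab <- unigrams
  repeat {
    if (length(vocab) >= max_size) break
    # count adjacent pairs across the corpus
    pairs <- unlist(lapply(seqs, function(s) {
      if (length(s) < 2L) return(character(0))
      paste(s[-length(s)], s[-1L], sep = "\x1f")
    }))
    if (!length(pairs)) break
    tab <- table(pairs)
    best_count <- max(tab)
    if (best_count < min_freq) break
    cands <- names(tab)[tab == best_count]
    merged <- vapply(strsplit(cands, "\x1f", fixed = TRUE),
                     function(p) paste0(p[1], p[2]), character(1))
    pick <- order(merged)[1]
    pair <- strsplit(cands[pick], "\x1f", fixed = TRUE)[[1]]
    tok <- merged[pick]
    seqs <- lapply(seqs, merge_pair, a = pair[1], b = pair[2], tok = tok)
    if (!(tok %in% vocab)) vocab <- c(vocab, tok)
  }
  structure(list(tokens = vocab, min_freq = as.integer(min_freq),
                 max_size = as.integer(max_size)),
            class = "espf_vocab")
}

# Replace non-overlapping left-to-right occurrences of (a, b) by tok.
merge_pair <- function(s, a, b, tok) {
  if (length(s) < 2L) return(s)
  out <- character(length(s))
  n <- 0L
  i <- 1L
  while (i <= length(s)) {
    if (i < length(s) && s[i] == a && s[i + 1L] == b) {
      n <- n + 1L
      out[n] <- tok
      i <- i + 2L
    } else {
      n <- n + 1L
      out[n] <- s[i]
      i <- i + 1L
    }
  }
  out[seq_len(n)]
}

#' Encode a SMILES string as a binary substructure-presence vector
#'
#' Greedy longest-match segmentation of the string into vocabulary tokens;
#' position j of the result is 1 iff token j occurs in the segmentation.
#' Characters not covered by any token are skipped. An empty or NA SMILES
#' yields a zero vector with a warning.
#'
#' @param smiles a single SMILES string.
#' @param vocab an [espf_fit()] vocabulary.
#' @return binary integer vector of length `length(vocab$tokens)`.
#' @export
espf_encode <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "espf_vocab"))
  out <- integer(length(vocab$tokens))
  if (is.na(smiles) || !nzchar(smiles)) {
    warning("espf_encode: empty SMILES, returning zero vector")
    return(out)
  }
  toks <- vocab$tokens
  ord <- order(-nchar(toks))
  i <- 1L
  n <- nchar(smiles)
  while (i <= n) {
    matched <- FALSE
    for (k in ord) {
      w <- nchar(toks[k])
      if (i + w - 1L <= n && substr(smiles, i, i + w - 1L) == toks[k]) {
        out[k] <- 1L
        i <- i + w
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  out
}
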