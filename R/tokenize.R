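#' Tokenize a sentence into normalized words
#'
#' Splits on whitespace, strips leading/trailing punctuation
#' (`.,!?;:"'()`) from each piece, case-folds, and drops pieces that become
#' empty. Hyphenated words are kept whole; interior apostrophes (as in
#' contractions) survive.
#'
#' @param text A sentence string (possibly empty).
#' @return Character vector of normalized words, in order.
#' @examples
#' tokenize("The BUCKETS HOLD WATER")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pieces <- strsplit(text, "[[:space:]]+")[[1L]]
  norm <- normalize_word(pieces)
  norm[nzchar(norm)]
}

# strip edge punctuation and case-fold (vectorized)
normalize_word <- function(x) {
  x <- gsub("^[.,!?;:\"'()]+|[.,!?;:\"'()]+$", "", x)
  tolower(x)
}

#' Build a tagged token sequence
#'
#' Resolves each word against the lexicon for its word class and root.
#' Words absent from the lexicon fall back to class `content` with
#' `root = norm` (unknown words are most often misspelled content words,
#' and the spell corrector runs before anything downstream depends on the
#' class). Forms of "to be" always get class `be_form`, whatever the
#' lexicon says.
#'
#' @param words Character vector of surface words (normalized or not).
#' @param lexicon A `spin_lexicon`.
#' @param is_keyword Optional logical vector flagging scoring keywords.
#' @return A `spin_tokens` object: list of parallel vectors `surface`,
#'   `norm`, `cls`, `root`, `is_keyword`.
#' @export
tag_tokens <- function(words, lexicon, is_keyword = NULL) {
  words <- as.character(words)
  if (is.null(is_keyword)) is_keyword <- rep(FALSE, length(words))
  stopifnot(length(is_keyword) == length(words))
  norm <- normalize_word(words)
  keep <- nzchar(norm)
  words <- words[keep]; norm <- norm[keep]; is_keyword <- is_keyword[keep]
  hit <- lexicon_lookup(norm, lexicon)
  new_tokens(words, norm, hit$cls, hit$root, is_keyword)
}

new_tokens <- function(surface, norm, cls, root, is_keyword) {
  structure(list(surface = surface, norm = norm, cls = cls, root = root,
                 is_keyword = as.logical(is_keyword)),
            class = "spin_tokens")
}

#' @export
length.spin_tokens <- function(x) length(x$norm)

#' @export
as.data.frame.spin_tokens <- function(x, ...) {
  data.frame(surface = x$surface, norm = x$norm, cls = x$cls,
             root = x$root, is_keyword = x$is_keyword,
             stringsAsFactors = FALSE)
}

#' @export
print.spin_tokens <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<spin_tokens> (empty)\n")
    return(invisible(x))
  }
  print(as.data.frame(x))
  invisible(x)
}

#' Parse a target sentence with uppercase keywords
#'
#' In BKB-style sentence lists the scoring keywords are written in
#' uppercase (e.g. "The BUCKETS HOLD WATER"). A word is flagged as a
#' keyword when it contains a letter and all its letters are uppercase.
#'
#' @param text Target sentence string.
#' @param lexicon A `spin_lexicon`.
#' @return A `spin_tokens` object with `is_keyword` set from case.
#' @export
parse_target <- function(text, lexicon) {
  pieces <- strsplit(text, "[[:space:]]+")[[1L]]
  pieces <- pieces[nzchar(pieces)]
  kw <- grepl("[[:upper:]]", pieces) & !grepl("[[:lower:]]", pieces)
  tag_tokens(pieces, lexicon, is_keyword = kw)
}

#' Apply the out-of-vocabulary spell-correction rule
#'
#' Response words missing from the lexicon's vocabulary are candidate
#' typos. Candidate corrections are all lexicon words at Levenshtein
#' distance 1, then (failing that) distance 2, each tier ordered by corpus
#' frequency (descending) then lexicographically; the word is replaced by
#' the first candidate whose norm equals the norm of a content-class
#' target token. Words already in the vocabulary are never touched, so
#' correctly spelled homophone confusions are kept as errors rather than
#' "fixed".
#'
#' @param response `spin_tokens` of the response sentence.
#' @param target `spin_tokens` of the (already tagged) target sentence.
#' @param lexicon A `spin_lexicon`.
#' @return A `spin_tokens` object of the same length, with corrected
#'   tokens re-tagged from the lexicon (surfaces are preserved).
#' @export
correct_spelling <- function(response, target, lexicon) {
  stopifnot(inherits(response, "spin_tokens"), inherits(target, "spin_tokens"))
  oov <- which(!(response$norm %in% lexicon$vocabulary))
  if (length(oov) == 0L) return(response)
  # the accepted candidate must equal a content-class target norm, so only
  # those norms (when they are lexicon words) can ever be chosen
  cand <- unique(target$norm[target$cls == "content"])
  cand <- cand[cand %in% lexicon$vocabulary]
  if (length(cand) == 0L) return(response)
  cand_freq <- lexicon$freq[match(cand, lexicon$word)]
  for (i in oov) {
    d <- drop(utils::adist(response$norm[i], cand))
    for (tier in 1:2) {
      hit <- which(d == tier)
      if (length(hit)) {
        pick <- hit[order(-cand_freq[hit], cand[hit])][1L]
        best <- cand[pick]
        look <- lexicon_lookup(best, lexicon)
        response$norm[i] <- best
        response$cls[i] <- look$cls
        response$root[i] <- look$root
        break
      }
    }
  }
  response
}
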