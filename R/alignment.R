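#' Alignment weight configuration
#'
#' Weights for the word-level global alignment. Defaults reward an exact
#' word match with +20 (chance agreement of whole words in the same slot
#' is low, so exact matches should dominate the alignment), a partial
#' match -- Levenshtein distance at most `partial_max_dist` (default 2) --
#' with +5 to keep morphologically or typographically perturbed words
#' aligned, and penalize mismatches and gaps at -5 each.
#'
#' @param match_reward Score for identical words.
#' @param partial_reward Score for near matches
#'   (0 < distance <= `partial_max_dist`).
#' @param mismatch_penalty Score for all other word pairings.
#' @param gap_penalty Score for aligning a word against a gap.
#' @param partial_max_dist Largest character edit distance still rewarded
#'   as a partial match.
#' @return A `word_weights` list.
#' @export
word_weights <- function(match_reward = 20L, partial_reward = 5L,
                         mismatch_penalty = -5L, gap_penalty = -5L,
                         partial_max_dist = 2L) {
  w <- list(match_reward = as.integer(match_reward),
            partial_reward = as.integer(partial_reward),
            mismatch_penalty = as.integer(mismatch_penalty),
            gap_penalty = as.integer(gap_penalty),
            partial_max_dist = as.integer(partial_max_dist))
  stopifnot(w$match_reward > w$partial_reward,
            w$partial_reward > w$mismatch_penalty,
            w$gap_penalty <= 0L, w$partial_max_dist >= 0L)
  class(w) <- "word_weights"
  w
}

#' Character-level Levenshtein distance
#'
#' Unit-cost edit distance: the number of single-character insertions,
#' deletions, or substitutions needed to turn one word into the other.
#'
#' @param a,b Word strings (vectorized; recycled to common length).
#' @return Integer vector of distances.
#' @examples
#' levenshtein("daughter", "daughters")
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  as.integer(diag(utils::adist(a, b)))
}

#' Score one word pairing
#'
#' `match_reward` for identical words, `partial_reward` for words within
#' `partial_max_dist` edits, otherwise `mismatch_penalty`.
#'
#' @param t,r Word strings.
#' @param w A [word_weights()] configuration.
#' @return Integer score.
#' @export
pair_score <- function(t, r, w = word_weights()) {
  d <- levenshtein(t, r)
  ifelse(t == r, w$match_reward,
         ifelse(d <= w$partial_max_dist, w$partial_reward,
                w$mismatch_penalty))
}

#' Word-level Needleman-Wunsch global alignment
#'
#' Aligns a target and a response sentence word-by-word, maximizing the
#' total score of word pairings (scored with [pair_score()] on normalized
#' forms) and gaps (scored with `gap_penalty`). Ties in the traceback are
#' broken deterministically: a word pairing is preferred over a gap in the
#' target, which is preferred over a gap in the response; this maximizes
#' the number of word pairings among equal-scoring alignments.
#'
#' @param target,response `spin_tokens` objects or character vectors of
#'   normalized words. Either may be empty.
#' @param w A [word_weights()] configuration.
#' @return A `word_alignment` object: list with `pairs` (a data frame with
#'   columns `target`, `response`, `kind`, `target_index`,
#'   `response_index`; `NA` marks a gap and `kind` is one of `match`,
#'   `partial`, `mismatch`, `target_gap`, `response_gap`), integer
#'   `score`, and the input token objects.
#' @examples
#' lex <- load_lexicon(spinerr_lexicon_path())
#' t <- tag_tokens(tokenize("the daughter set the table"), lex)
#' r <- tag_tokens(tokenize("the daughters set the table"), lex)
#' align_words(t, r)
#' @export
align_words <- function(target, response, w = word_weights()) {
  tt <- if (inherits(target, "spin_tokens")) target else
    tag_free_tokens(target)
  rt <- if (inherits(response, "spin_tokens")) response else
    tag_free_tokens(response)
  tn <- tt$norm
  rn <- rt$norm
  n <- length(tn); m <- length(rn)
  g <- w$gap_penalty

  if (n == m && (n == 0L || all(tn == rn))) {
    # identical sequences: the all-match diagonal is optimal
    # (every pairing earns the maximal per-pair score and no gaps are paid)
    return(new_alignment(seq_len(n), seq_len(n),
                         rep("match", n), n * w$match_reward, tt, rt, w))
  }

  S <- NULL
  if (n > 0L && m > 0L) {
    d <- utils::adist(tn, rn)
    S <- matrix(w$mismatch_penalty, n, m)
    S[d <= w$partial_max_dist] <- w$partial_reward
    S[d == 0L] <- w$match_reward
  }
  M <- matrix(0L, n + 1L, m + 1L)
  M[, 1L] <- (0:n) * g
  M[1L, ] <- (0:m) * g
  if (n > 0L && m > 0L) {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        M[i + 1L, j + 1L] <- max(M[i, j] + S[i, j],
                                 M[i + 1L, j] + g,
                                 M[i, j + 1L] + g)
      }
    }
  }
  # traceback, preferring diagonal > target gap > response gap
  ti <- integer(0); ri <- integer(0); kind <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && M[i + 1L, j + 1L] == M[i, j] + S[i, j]) {
      k <- if (tn[i] == rn[j]) "match" else
        if (S[i, j] == w$partial_reward) "partial" else "mismatch"
      ti <- c(i, ti); ri <- c(j, ri); kind <- c(k, kind)
      i <- i - 1L; j <- j - 1L
    } else if (j > 0L && M[i + 1L, j + 1L] == M[i + 1L, j] + g) {
      ti <- c(NA_integer_, ti); ri <- c(j, ri)
      kind <- c("target_gap", kind)
      j <- j - 1L
    } else {
      ti <- c(i, ti); ri <- c(NA_integer_, ri)
      kind <- c("response_gap", kind)
      i <- i - 1L
    }
  }
  new_alignment(ti, ri, kind, M[n + 1L, m + 1L], tt, rt, w)
}

# wrap a bare character vector so alignment consumers have a uniform shape
tag_free_tokens <- function(x) {
  x <- as.character(x)
  new_tokens(x, x, rep("content", length(x)), x, rep(FALSE, length(x)))
}

new_alignment <- function(ti, ri, kind, score, target_tokens,
                          response_tokens, weights) {
  structure(list(target_index = ti, response_index = ri, kind = kind,
                 score = as.integer(score),
                 target_tokens = target_tokens,
                 response_tokens = response_tokens,
                 weights = weights),
            class = "word_alignment")
}

#' Aligned pairs as a data frame
#'
#' @param alignment A `word_alignment`.
#' @return Data frame with columns `target`, `response` (`NA` marks a
#'   gap), `kind`, `target_index`, `response_index`.
#' @export
alignment_pairs <- function(alignment) {
  ti <- alignment$target_index
  ri <- alignment$response_index
  data.frame(
    target = alignment$target_tokens$norm[ti],
    response = alignment$response_tokens$norm[ri],
    kind = alignment$kind,
    target_index = ti,
    response_index = ri,
    stringsAsFactors = FALSE)
}

#' @export
print.word_alignment <- function(x, ...) {
  cat("<word_alignment> score =", x$score, "\n")
  p <- alignment_pairs(x)
  cat(" target  :", paste(ifelse(is.na(p$target), "_", p$target),
                          collapse = " "), "\n")
  cat(" response:", paste(ifelse(is.na(p$response), "_", p$response),
                          collapse = " "), "\n")
  cat(" kinds   :", paste(abbreviate(p$kind, 5), collapse = " "), "\n")
  invisible(x)
}
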