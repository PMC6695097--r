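# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately written without reusing the package's
# implementation paths (plain recursions, full enumerations), so the tests
# check the implementation against an independent route.

fixture_lexicon <- local({
  lex <- NULL
  function() {
    if (is.null(lex)) lex <<- load_lexicon(spinerr_lexicon_path())
    lex
  }
})

# plain recursive Levenshtein with memoization on prefix lengths
lev_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- min(rec(i - 1, j) + 1,
               rec(i, j - 1) + 1,
               rec(i - 1, j - 1) + (av[i] != bv[j]))
    memo[[key]] <- res
    res
  }
  rec(length(av), length(bv))
}

# score a single word pairing, independent of pair_score()
pair_score_oracle <- function(t, r, w) {
  if (t == r) return(w$match_reward)
  if (lev_oracle(t, r) <= w$partial_max_dist) return(w$partial_reward)
  w$mismatch_penalty
}

# maximal gapped-alignment score by exhaustive memoized recursion over the
# three moves at every position (independent of the package's DP/traceback)
best_score_oracle <- function(tn, rn, w = word_weights()) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i > 0 && j > 0) {
      best <- max(best, rec(i - 1, j - 1) + pair_score_oracle(tn[i], rn[j], w))
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + w$gap_penalty)
    if (j > 0) best <- max(best, rec(i, j - 1) + w$gap_penalty)
    memo[[key]] <- best
    best
  }
  rec(length(tn), length(rn))
}

# every legal gapped alignment as a two-column matrix of indices (NA = gap),
# built by explicit enumeration; used on short sentences only
enumerate_alignments <- function(n, m) {
  if (n == 0 && m == 0) return(list(matrix(integer(0), ncol = 2)))
  out <- list()
  if (n > 0 && m > 0) {
    for (al in enumerate_alignments(n - 1, m - 1)) {
      out[[length(out) + 1]] <- rbind(al, c(n, m))
    }
  }
  if (n > 0) {
    for (al in enumerate_alignments(n - 1, m)) {
      out[[length(out) + 1]] <- rbind(al, c(n, NA))
    }
  }
  if (m > 0) {
    for (al in enumerate_alignments(n, m - 1)) {
      out[[length(out) + 1]] <- rbind(al, c(NA, m))
    }
  }
  out
}

score_enumerated <- function(al, tn, rn, w) {
  s <- 0
  for (k in seq_len(nrow(al))) {
    i <- al[k, 1]; j <- al[k, 2]
    s <- s + if (is.na(i) || is.na(j)) w$gap_penalty else
      pair_score_oracle(tn[i], rn[j], w)
  }
  s
}

# the nine canonical worked error-type examples: one row per example with
# the single error field expected to be non-zero (or the DNH status)
worked_examples <- function() {
  data.frame(
    label = c("dnh_nothing", "dnh_incorrect",
              "omission_content", "omission_function",
              "addition_content", "addition_function",
              "substitution_content", "substitution_function",
              "morpheme"),
    target = c("he BROKE his LEG",
               "the DAUGHTER SET the TABLE",
               "a MAN is TURNING the FAUCET",
               "a MAN is TURNING the FAUCET",
               "a MAN is TURNING the FAUCET",
               "FATHER FORGOT the BREAD",
               "the BOY HURRIED to SCHOOL",
               "a MAN is TURNING the FAUCET",
               "the DAUGHTER SET the TABLE"),
    response = c("",
                 "can go very fast",
                 "is turning the faucet",
                 "is turning the faucet",
                 "a man is turning the faucet trees",
                 "the father forgot the bread",
                 "the boy went to school",
                 "the man is turning the faucet",
                 "the daughters set the table"),
    stringsAsFactors = FALSE)
}

# expected non-DNH error profile per worked example (the two omission rows
# share one aligned sentence pair, so each shows both omissions)
worked_expected <- function() {
  zero <- c(content_sub = 0L, content_add = 0L, content_om = 0L,
            function_sub = 0L, function_add = 0L, function_om = 0L,
            morpheme_errors = 0L)
  list(
    omission_content = replace(zero, c("content_om", "function_om"), 1L),
    omission_function = replace(zero, c("content_om", "function_om"), 1L),
    addition_content = replace(zero, "content_add", 1L),
    addition_function = replace(zero, "function_add", 1L),
    substitution_content = replace(zero, "content_sub", 1L),
    substitution_function = replace(zero, "function_sub", 1L),
    morpheme = replace(zero, "morpheme_errors", 1L))
}

error_profile <- function(ts) {
  c(content_sub = ts$content_sub, content_add = ts$content_add,
    content_om = ts$content_om, function_sub = ts$function_sub,
    function_add = ts$function_add, function_om = ts$function_om,
    morpheme_errors = ts$morpheme_errors)
}
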