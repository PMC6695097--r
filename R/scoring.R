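#' Score keywords of a trial
#'
#' A keyword is correct iff its exact normalized form appears among the
#' response words, position-independently, with each response word
#' consumable at most once. Morphological variants (any morpheme added or
#' deleted) are incorrect.
#'
#' @param target `spin_tokens` with `is_keyword` flags.
#' @param response `spin_tokens` of the (spell-corrected) response.
#' @return Logical vector, one element per keyword, in target order.
#' @export
score_keywords <- function(target, response) {
  kw <- target$norm[target$is_keyword]
  pool <- response$norm
  correct <- logical(length(kw))
  for (k in seq_along(kw)) {
    j <- match(kw[k], pool)
    if (!is.na(j)) {
      correct[k] <- TRUE
      pool <- pool[-j]
    }
  }
  correct
}

#' Classify whole-sentence omission (DNH) status
#'
#' A trial is "Did Not Hear" when the response contains no content word
#' whose root matches the root of any content word of the target (forms
#' of "to be" are not content words for this purpose). DNH trials split
#' into `dnh_nothing` (no content words transcribed at all) and
#' `dnh_incorrect` (content words transcribed, but none from the target).
#' Any root-level match makes the status `none`.
#'
#' @param target,response `spin_tokens` (tagged; response spell-corrected).
#' @return One of `"none"`, `"dnh_nothing"`, `"dnh_incorrect"`.
#' @export
classify_dnh <- function(target, response) {
  t_roots <- target$root[target$cls == "content"]
  r_content <- response$cls == "content"
  if (any(r_content) && any(response$root[r_content] %in% t_roots)) {
    return("none")
  }
  if (!any(r_content)) "dnh_nothing" else "dnh_incorrect"
}

#' Masker overlap of a DNH-Incorrect response
#'
#' For a DNH-Incorrect trial in the intelligible-masker (1T) condition,
#' counts how many of the response's content words come from the masker
#' sentences, matched at root level.
#'
#' @param response `spin_tokens` of the response.
#' @param masker_roots Character vector: the masker inventory as a set of
#'   content-word roots (or norms, see [masker_root_inventory()]).
#' @param dnh_status The trial's DNH status; must be `"dnh_incorrect"`.
#' @param condition The trial's masker condition; must be `"1T"`.
#' @param level Match at `"root"` (default) or `"surface"` level; must
#'   agree with how the inventory was built.
#' @return List with integer `matched` and `total` content words.
#' @export
masker_overlap <- function(response, masker_roots,
                           dnh_status = "dnh_incorrect", condition = "1T",
                           level = c("root", "surface")) {
  level <- match.arg(level)
  if (!identical(dnh_status, "dnh_incorrect")) {
    stop("masker_overlap is defined only for DNH-Incorrect trials")
  }
  if (!identical(condition, "1T")) {
    stop("masker_overlap is defined only for the 1T condition")
  }
  keep <- response$cls == "content"
  r <- if (level == "root") response$root[keep] else response$norm[keep]
  list(matched = sum(r %in% masker_roots), total = length(r))
}

# be-forms count with function words in word-level error attribution
word_class <- function(cls) ifelse(cls == "be_form", "function", cls)

#' Count word-level errors from an alignment
#'
#' Walks the aligned pairs: a response word against a target gap is an
#' addition (attributed to the response word's class); a target word
#' against a response gap is an omission (attributed to the target word's
#' class); two non-identical function words are a function substitution;
#' two content words with different roots are a content substitution
#' (content pairs sharing a root are morpheme-level errors, not word
#' errors); a content word paired with a function word is a substitution
#' attributed to the target word's class. Be-forms count as function
#' words.
#'
#' @param alignment A `word_alignment` built from tagged tokens.
#' @return Named integer vector with elements `content_sub`,
#'   `content_add`, `content_om`, `function_sub`, `function_add`,
#'   `function_om`.
#' @export
score_word_errors <- function(alignment) {
  kind <- alignment$kind
  ti <- alignment$target_index
  ri <- alignment$response_index
  t_cls <- word_class(alignment$target_tokens$cls)
  r_cls <- word_class(alignment$response_tokens$cls)
  t_root <- alignment$target_tokens$root
  r_root <- alignment$response_tokens$root

  add <- kind == "target_gap"
  om <- kind == "response_gap"
  paired <- kind == "partial" | kind == "mismatch"
  # substitutions: two function words (not identical), two content words
  # with different roots, or a cross-class pair attributed to the target
  # word's class; content pairs sharing a root are morpheme errors instead
  tc <- t_cls[ti[paired]]
  rc <- r_cls[ri[paired]]
  root_differs <- t_root[ti[paired]] != r_root[ri[paired]]
  sub_cls <- character(0)
  if (any(paired)) {
    keep <- tc != "content" | rc != "content" | root_differs
    sub_cls <- tc[keep]
  }
  c(content_sub = sum(sub_cls == "content"),
    content_add = sum(r_cls[ri[add]] == "content"),
    content_om = sum(t_cls[ti[om]] == "content"),
    function_sub = sum(sub_cls == "function"),
    function_add = sum(r_cls[ri[add]] == "function"),
    function_om = sum(t_cls[ti[om]] == "function"))
}

#' Count morpheme-level errors from an alignment
#'
#' An aligned pair of two content words whose surface (normalized) forms
#' differ but whose roots are equal is one morphemic error (tense change,
#' pluralization, ...). Pairs with unequal roots are word substitutions
#' instead; a pair is never both.
#'
#' @param alignment A `word_alignment` built from tagged tokens.
#' @return Integer count.
#' @export
score_morpheme_errors <- function(alignment) {
  paired <- alignment$kind == "partial" | alignment$kind == "mismatch"
  ti <- alignment$target_index[paired]
  ri <- alignment$response_index[paired]
  tt <- alignment$target_tokens
  rt <- alignment$response_tokens
  sum(tt$cls[ti] == "content" & rt$cls[ri] == "content" &
        tt$root[ti] == rt$root[ri])
}

#' Score one trial end to end
#'
#' Runs the full per-trial pipeline: tokenize and tag both sentences,
#' spell-correct the response, score keywords, classify DNH status; for
#' non-DNH trials additionally align the sentences and count word- and
#' morpheme-level errors; for DNH-Incorrect trials in the 1T condition
#' compute masker overlap. DNH trials carry no word/morpheme counts
#' (they are excluded from those analyses downstream).
#'
#' @param target Target sentence string, keywords in uppercase (or an
#'   already parsed `spin_tokens` object).
#' @param response Typed response sentence string.
#' @param lexicon A `spin_lexicon`.
#' @param condition Masker condition label (e.g. `"1T"`, `"1T_tr"`,
#'   `"SSN"`).
#' @param w A [word_weights()] configuration.
#' @param masker_roots Optional masker root inventory for masker-overlap
#'   scoring (used only for DNH-Incorrect 1T trials).
#' @param masker_level Level of masker matching, `"root"` (default) or
#'   `"surface"`; must agree with how `masker_roots` was built.
#' @return A `trial_score` list: `keyword_correct` (logical vector),
#'   `dnh_status`, `masker_matched`/`masker_total` (NA when not
#'   applicable), the six word-error counts, `morpheme_errors`,
#'   `n_target_tokens`, `n_response_tokens`, and the `alignment` (NULL
#'   for DNH trials).
#' @examples
#' lex <- load_lexicon(spinerr_lexicon_path())
#' score_trial("the DAUGHTER SET the TABLE", "the daughters set the table",
#'             lex)
#' @export
score_trial <- function(target, response, lexicon, condition = "1T",
                        w = word_weights(), masker_roots = NULL,
                        masker_level = c("root", "surface")) {
  masker_level <- match.arg(masker_level)
  tt <- if (inherits(target, "spin_tokens")) target else
    parse_target(target, lexicon)
  rt <- tag_tokens(tokenize(response), lexicon)
  rt <- correct_spelling(rt, tt, lexicon)
  keyword_correct <- score_keywords(tt, rt)
  dnh <- classify_dnh(tt, rt)

  counts <- rep(NA_integer_, 6L)
  names(counts) <- c("content_sub", "content_add", "content_om",
                     "function_sub", "function_add", "function_om")
  morph <- NA_integer_
  matched <- NA_integer_; total <- NA_integer_
  alignment <- NULL
  if (dnh == "none") {
    alignment <- align_words(tt, rt, w)
    counts <- score_word_errors(alignment)
    morph <- score_morpheme_errors(alignment)
  } else if (dnh == "dnh_incorrect" && identical(condition, "1T") &&
             !is.null(masker_roots)) {
    ov <- masker_overlap(rt, masker_roots, dnh, condition,
                         level = masker_level)
    matched <- ov$matched; total <- ov$total
  }
  structure(list(keyword_correct = keyword_correct,
                 dnh_status = dnh,
                 masker_matched = matched, masker_total = total,
                 content_sub = counts[["content_sub"]],
                 content_add = counts[["content_add"]],
                 content_om = counts[["content_om"]],
                 function_sub = counts[["function_sub"]],
                 function_add = counts[["function_add"]],
                 function_om = counts[["function_om"]],
                 morpheme_errors = morph,
                 n_target_tokens = length(tt),
                 n_response_tokens = length(rt),
                 alignment = alignment),
            class = "trial_score")
}

#' @export
print.trial_score <- function(x, ...) {
  cat("<trial_score>\n")
  cat(" keywords correct:", sum(x$keyword_correct), "/",
      length(x$keyword_correct),
      paste0("(", paste(x$keyword_correct, collapse = " "), ")"), "\n")
  cat(" dnh_status:", x$dnh_status, "\n")
  if (!is.na(x$masker_total)) {
    cat(" masker overlap:", x$masker_matched, "/", x$masker_total, "\n")
  }
  if (!is.na(x$content_sub)) {
    cat(sprintf(" word errors: content S/A/O %d/%d/%d, function S/A/O %d/%d/%d\n",
                x$content_sub, x$content_add, x$content_om,
                x$function_sub, x$function_add, x$function_om))
    cat(" morpheme errors:", x$morpheme_errors, "\n")
    print(x$alignment)
  }
  invisible(x)
}

#' Score a table of trials
#'
#' Applies [score_trial()] to every row of a trial table and returns one
#' row of outcomes per trial.
#'
#' @param trials Data frame with columns `subject_id`, `group`,
#'   `condition`, `target`, `response` (and optionally `masker_id`).
#' @param lexicon A `spin_lexicon`.
#' @param w A [word_weights()] configuration.
#' @param masker_roots Optional masker root inventory (see
#'   [masker_root_inventory()]).
#' @param masker_level Level of masker matching, `"root"` or `"surface"`.
#' @param keep_alignments If `TRUE`, attach the list of per-trial
#'   `trial_score` objects as attribute `"details"` (used when writing
#'   per-trial JSON-lines output).
#' @return Data frame with one row per trial: identifiers, keyword
#'   counts, DNH status, masker overlap counts, and error counts.
#' @export
score_trials <- function(trials, lexicon, w = word_weights(),
                         masker_roots = NULL,
                         masker_level = c("root", "surface"),
                         keep_alignments = FALSE) {
  masker_level <- match.arg(masker_level)
  need <- c("subject_id", "group", "condition", "target", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table lacks column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(trials)
  if (n == 0L) stop("trial table is empty")
  # targets repeat across subjects; parse each distinct one once
  utext <- unique(trials$target)
  parsed <- lapply(utext, parse_target, lexicon = lexicon)
  names(parsed) <- utext
  details <- vector("list", n)
  for (i in seq_len(n)) {
    details[[i]] <- score_trial(parsed[[trials$target[i]]],
                                trials$response[i],
                                lexicon, condition = trials$condition[i],
                                w = w, masker_roots = masker_roots,
                                masker_level = masker_level)
  }
  out <- data.frame(
    subject_id = trials$subject_id,
    group = trials$group,
    condition = trials$condition,
    n_keywords = vapply(details, function(d) length(d$keyword_correct), 0L),
    n_keywords_correct = vapply(details,
                                function(d) sum(d$keyword_correct), 0L),
    dnh_status = vapply(details, function(d) d$dnh_status, ""),
    masker_matched = vapply(details, function(d) d$masker_matched, 0L),
    masker_total = vapply(details, function(d) d$masker_total, 0L),
    content_sub = vapply(details, function(d) d$content_sub, 0L),
    content_add = vapply(details, function(d) d$content_add, 0L),
    content_om = vapply(details, function(d) d$content_om, 0L),
    function_sub = vapply(details, function(d) d$function_sub, 0L),
    function_add = vapply(details, function(d) d$function_add, 0L),
    function_om = vapply(details, function(d) d$function_om, 0L),
    morpheme_errors = vapply(details, function(d) d$morpheme_errors, 0L),
    stringsAsFactors = FALSE)
  if (keep_alignments) attr(out, "details") <- details
  out
}
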