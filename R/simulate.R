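#' Session design constants
#'
#' The design the generator emulates: three masker conditions (one
#' intelligible competing talker, the same talker time-reversed, and
#' speech-shaped noise), one 16-sentence BKB-style list per condition with
#' 50 scoring keywords (each sentence carrying 3 or 4), a 30-sentence
#' masker inventory for the competing talker, and a -5 dB signal-to-noise
#' ratio carried as metadata only (no audio is ever synthesized).
#'
#' @param conditions Masker condition labels.
#' @param sentences_per_list Sentences per condition list.
#' @param keywords_per_list Total scoring keywords per list.
#' @param masker_sentences Sentences in the competing-talker inventory.
#' @param snr_db Signal-to-noise ratio metadata, in dB.
#' @return A `session_design` list.
#' @export
session_design <- function(conditions = c("1T", "1T_tr", "SSN"),
                           sentences_per_list = 16L,
                           keywords_per_list = 50L,
                           masker_sentences = 30L,
                           snr_db = -5) {
  structure(list(conditions = conditions,
                 sentences_per_list = as.integer(sentences_per_list),
                 keywords_per_list = as.integer(keywords_per_list),
                 masker_sentences = as.integer(masker_sentences),
                 snr_db = snr_db),
            class = "session_design")
}

#' Generator vocabularies
#'
#' The word pools the synthetic generator builds sentences from. Every
#' word (and its lexicon siblings) is in the packaged lexicon, and the
#' target, masker, and decoy content pools are pairwise disjoint, so the
#' masker-intrusion rate is identifiable from the overlap statistic.
#'
#' @return Named list of character vectors: `target_nouns`,
#'   `target_verbs`, `target_adjs`, `masker_nouns`, `masker_verbs`,
#'   `decoys`, `function_words`.
#' @export
sim_vocab <- function() {
  list(
    target_nouns = c("bucket", "daughter", "table", "farmer", "garden",
                     "window", "letter", "dinner", "wagon", "sister",
                     "brother", "ticket", "jacket", "kitchen", "puppy",
                     "orange"),
    target_verbs = c("held", "set", "turned", "carried", "cleaned",
                     "found", "dropped", "washed", "opened", "closed",
                     "painted", "broke", "hurried", "forgot", "saw",
                     "heard"),
    target_adjs = c("big", "small", "red", "green", "old", "new",
                    "little", "heavy"),
    masker_nouns = c("dessert", "apple", "pie", "ocean", "pirate",
                     "cloud", "thunder", "guitar", "piano", "doctor",
                     "nurse", "mountain", "river", "boat", "song"),
    masker_verbs = c("sailed", "sang", "danced", "climbed", "cooked",
                     "rode", "swam", "played"),
    decoys = c("unicorn", "dragon", "wizard", "comet", "volcano",
               "jungle", "robot", "castle", "galaxy", "meteor",
               "goblin", "lantern", "marble", "anchor", "turnip",
               "walrus", "zebra", "igloo", "kayak", "pebble"),
    function_words = c("the", "a", "an", "his", "her", "their", "to",
                       "on", "in", "at", "with", "for", "of", "and",
                       "some", "this", "that", "he", "she", "they",
                       "we", "it", "you"))
}

#' Morphological siblings of content words
#'
#' Maps each content word of the lexicon to the other content words that
#' share its root (e.g. `held` to `hold`/`holds`): the pool the
#' generator's morpheme-flip process draws from, and the definition of
#' which words are eligible for a morphemic error at all.
#'
#' @param lexicon A `spin_lexicon`.
#' @return Named list: word -> character vector of siblings (possibly
#'   empty).
#' @export
morph_siblings <- function(lexicon) {
  content <- lexicon$cls == "content"
  words <- lexicon$word[content]
  roots <- lexicon$root[content]
  sib <- lapply(seq_along(words), function(i) {
    s <- words[roots == roots[i]]
    s[s != words[i]]
  })
  names(sib) <- words
  sib
}

#' Generate BKB-style target lists and a masker inventory
#'
#' Builds one 16-sentence list per condition from simple determiner +
#' noun + verb + noun templates (with an adjective slot for 4-keyword
#' sentences), keywords uppercase, summing to exactly
#' `keywords_per_list` per list; and a 30-sentence masker inventory
#' drawn from a content vocabulary disjoint from the target vocabulary.
#' Fully reproducible from `seed`.
#'
#' @param design A [session_design()].
#' @param lexicon A `spin_lexicon` containing the generator vocabulary.
#' @param seed Integer seed.
#' @return List with `targets` (data frame: `condition`, `sentence_id`,
#'   `text`, `n_keywords`), `maskers` (character vector), and `design`.
#' @export
generate_materials <- function(design = session_design(),
                               lexicon = load_lexicon(spinerr_lexicon_path()),
                               seed = 1L) {
  v <- sim_vocab()
  vocab_missing <- setdiff(unlist(v), lexicon$vocabulary)
  if (length(vocab_missing)) {
    stop("lexicon lacks generator vocabulary: ",
         paste(utils::head(vocab_missing, 5), collapse = ", "))
  }
  n_sent <- design$sentences_per_list
  # 3 keywords per sentence, plus one extra (an adjective) on enough
  # sentences to reach the list total
  n_extra <- design$keywords_per_list - 3L * n_sent
  if (n_extra < 0L || n_extra > n_sent) {
    stop("keywords_per_list is not reachable with 3-4 keywords per sentence")
  }
  set.seed(seed)
  targets <- do.call(rbind, lapply(design$conditions, function(cond) {
    four_kw <- seq_len(n_sent) %in% sample.int(n_sent, n_extra)
    rows <- lapply(seq_len(n_sent), function(i) {
      nouns <- sample(v$target_nouns, 2L)
      verb <- sample(v$target_verbs, 1L)
      if (four_kw[i]) {
        adj <- sample(v$target_adjs, 1L)
        text <- paste("the", toupper(adj), toupper(nouns[1L]),
                      toupper(verb), "the", toupper(nouns[2L]))
      } else {
        text <- paste("the", toupper(nouns[1L]), toupper(verb),
                      "the", toupper(nouns[2L]))
      }
      data.frame(condition = cond, sentence_id = i, text = text,
                 n_keywords = 3L + four_kw[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  maskers <- vapply(seq_len(design$masker_sentences), function(i) {
    nouns <- sample(v$masker_nouns, 2L)
    verb <- sample(v$masker_verbs, 1L)
    paste("the", nouns[1L], verb, "the", nouns[2L])
  }, "")
  list(targets = targets, maskers = maskers, design = design)
}

#' Simulation parameters for one cohort
#'
#' One row per group-by-condition cell. `keyword_hit_rate` is the target
#' marginal keyword accuracy of the cell; the simulator converts it
#' internally into a per-keyword knockout probability that accounts for
#' the cell's DNH and word-error rates. `dnh_nothing_rate` is the
#' probability of an empty response; `dnh_incorrect_rate` the probability
#' (given not DNH-Nothing) of a response made only of non-target content
#' words, each drawn from the masker inventory with probability
#' `masker_intrusion_prob` (otherwise from a decoy vocabulary). The
#' remaining rates are independent per-word probabilities applied when
#' the listener "hears" the sentence: substitution, addition, omission
#' for content and function words separately, morpheme flips (content
#' words with a lexicon sibling), and 1-edit typos.
#'
#' @param groups,conditions Labels of the cells to cover.
#' @param keyword_hit_rate,dnh_nothing_rate,dnh_incorrect_rate,masker_intrusion_prob
#'   Per-trial / per-word probabilities, recycled over cells.
#' @param content_sub_rate,content_add_rate,content_om_rate Per-word rates
#'   for content words.
#' @param function_sub_rate,function_add_rate,function_om_rate Per-word
#'   rates for function words.
#' @param morpheme_rate,typo_rate Per-word rates.
#' @return Data frame of class `sim_params`.
#' @export
sim_params <- function(groups = c("MDD", "control"),
                       conditions = c("1T", "1T_tr", "SSN"),
                       keyword_hit_rate = 1, dnh_nothing_rate = 0,
                       dnh_incorrect_rate = 0, masker_intrusion_prob = 0,
                       content_sub_rate = 0, content_add_rate = 0,
                       content_om_rate = 0, function_sub_rate = 0,
                       function_add_rate = 0, function_om_rate = 0,
                       morpheme_rate = 0, typo_rate = 0) {
  grid <- expand.grid(group = groups, condition = conditions,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  p <- data.frame(grid,
                  keyword_hit_rate = rep_len(keyword_hit_rate, n),
                  dnh_nothing_rate = rep_len(dnh_nothing_rate, n),
                  dnh_incorrect_rate = rep_len(dnh_incorrect_rate, n),
                  masker_intrusion_prob = rep_len(masker_intrusion_prob, n),
                  content_sub_rate = rep_len(content_sub_rate, n),
                  content_add_rate = rep_len(content_add_rate, n),
                  content_om_rate = rep_len(content_om_rate, n),
                  function_sub_rate = rep_len(function_sub_rate, n),
                  function_add_rate = rep_len(function_add_rate, n),
                  function_om_rate = rep_len(function_om_rate, n),
                  morpheme_rate = rep_len(morpheme_rate, n),
                  typo_rate = rep_len(typo_rate, n),
                  stringsAsFactors = FALSE)
  validate_sim_params(p)
}

#' @rdname sim_params
#' @param params A `sim_params` data frame to validate.
#' @export
validate_sim_params <- function(params) {
  rate_cols <- setdiff(names(params), c("group", "condition"))
  for (col in rate_cols) {
    x <- params[[col]]
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
      stop("invalid probability in field '", col,
           "': values must lie in [0, 1]")
    }
  }
  if (any(params$dnh_nothing_rate + params$dnh_incorrect_rate > 1)) {
    stop("dnh_nothing_rate + dnh_incorrect_rate must not exceed 1")
  }
  attr(params, "out.attrs") <- NULL
  rownames(params) <- NULL
  class(params) <- c("sim_params", "data.frame")
  params
}

#' Study-emulating default simulation parameters
#'
#' Cell-level rates chosen to emulate the group-by-condition pattern of a
#' clinical speech-in-noise study: keyword accuracy around 65-86%, a
#' DNH-Incorrect excess for the clinical group under the intelligible
#' competing talker (26.5% vs 16.3%), low DNH-Nothing rates, and ~70%
#' masker intrusion among DNH-Incorrect content words in the 1T
#' condition. Word-level rates are small and vary qualitatively by
#' condition (morpheme errors highest in stationary noise).
#'
#' @return A `sim_params` data frame.
#' @export
default_sim_params <- function() {
  p <- expand.grid(group = c("MDD", "control"),
                   condition = c("1T", "1T_tr", "SSN"),
                   stringsAsFactors = FALSE)
  num <- function(mdd_1t, c_1t, mdd_tr, c_tr, mdd_ssn, c_ssn) {
    c(mdd_1t, c_1t, mdd_tr, c_tr, mdd_ssn, c_ssn)
  }
  p$keyword_hit_rate      <- num(0.652, 0.750, 0.815, 0.863, 0.738, 0.772)
  p$dnh_nothing_rate      <- num(0.010, 0.011, 0.054, 0.021, 0.051, 0.043)
  p$dnh_incorrect_rate    <- num(0.265, 0.163, 0.044, 0.038, 0.052, 0.034)
  p$masker_intrusion_prob <- num(0.710, 0.723, 0, 0, 0, 0)
  p$content_sub_rate      <- num(0.040, 0.035, 0.020, 0.018, 0.040, 0.035)
  p$content_add_rate      <- num(0.010, 0.008, 0.005, 0.005, 0.010, 0.008)
  p$content_om_rate       <- num(0.040, 0.035, 0.020, 0.018, 0.040, 0.035)
  p$function_sub_rate     <- num(0.030, 0.025, 0.015, 0.012, 0.030, 0.025)
  p$function_add_rate     <- num(0.020, 0.015, 0.010, 0.008, 0.020, 0.015)
  p$function_om_rate      <- num(0.050, 0.040, 0.025, 0.020, 0.050, 0.040)
  p$morpheme_rate         <- num(0.030, 0.030, 0.020, 0.020, 0.080, 0.080)
  p$typo_rate             <- num(0.020, 0.020, 0.020, 0.020, 0.020, 0.020)
  validate_sim_params(p)
}

# precompute everything simulate_response needs about a target sentence
prepare_sim_target <- function(text, lexicon, siblings = NULL) {
  pieces <- strsplit(text, "[[:space:]]+")[[1L]]
  pieces <- pieces[nzchar(pieces)]
  kw <- grepl("[[:upper:]]", pieces) & !grepl("[[:lower:]]", pieces)
  norm <- normalize_word(pieces)
  keep <- nzchar(norm)
  norm <- norm[keep]; kw <- kw[keep]
  cls <- word_class(lexicon_lookup(norm, lexicon)$cls)
  if (is.null(siblings)) siblings <- morph_siblings(lexicon)
  sib <- lapply(norm, function(w) {
    s <- siblings[[w]]
    if (is.null(s)) character(0) else s
  })
  list(norm = norm, cls = cls, is_keyword = kw, siblings = sib)
}

#' Simulate one typed listener response
#'
#' Draws a response for one trial under the generative model described in
#' [sim_params()]: a whole-sentence omission (empty response), a
#' DNH-Incorrect response of masker/decoy content words, or a copy of the
#' target perturbed by independent per-word substitution, addition,
#' omission, morpheme-flip and typo processes. Uses the current RNG
#' state; seed at the cohort level for reproducibility.
#'
#' @param target Target sentence text (keywords uppercase) or a prepared
#'   target from the internal preparation step.
#' @param params_row One row of a `sim_params` data frame.
#' @param lexicon A `spin_lexicon`.
#' @param masker_words Content surfaces available as masker intrusions.
#' @param decoy_words Content surfaces for non-masker irrelevant words.
#' @return Response sentence string (possibly empty).
#' @export
simulate_response <- function(target, params_row, lexicon,
                              masker_words, decoy_words) {
  pr <- params_row
  if (is.character(target)) target <- prepare_sim_target(target, lexicon)
  if (stats::runif(1) < pr$dnh_nothing_rate) return("")
  if (stats::runif(1) < pr$dnh_incorrect_rate) {
    k <- sample(2:4, 1L)
    from_masker <- stats::runif(k) < pr$masker_intrusion_prob
    words <- ifelse(from_masker,
                    sample(masker_words, k, replace = TRUE),
                    sample(decoy_words, k, replace = TRUE))
    return(paste(words, collapse = " "))
  }

  # conditional keyword knockout so keyword_hit_rate is (approximately)
  # the marginal accuracy of the cell
  p_dnh <- pr$dnh_nothing_rate + (1 - pr$dnh_nothing_rate) *
    pr$dnh_incorrect_rate
  survive <- (1 - p_dnh) *
    (1 - pr$content_sub_rate - pr$content_om_rate - pr$morpheme_rate)
  p_miss <- if (survive > 0) max(0, 1 - pr$keyword_hit_rate / survive) else 0

  out <- character(0)
  funs <- sim_vocab()$function_words
  for (i in seq_along(target$norm)) {
    w <- target$norm[i]
    cls <- target$cls[i]
    if (target$is_keyword[i] && stats::runif(1) < p_miss) {
      if (stats::runif(1) < 0.5) {
        out <- c(out, sample(decoy_words, 1L))
      } # else omitted
    } else {
      om <- if (cls == "content") pr$content_om_rate else
        pr$function_om_rate
      sub <- if (cls == "content") pr$content_sub_rate else
        pr$function_sub_rate
      if (stats::runif(1) >= om) {
        if (stats::runif(1) < sub) {
          w <- if (cls == "content") sample(decoy_words, 1L) else
            sample(setdiff(funs, w), 1L)
        } else if (cls == "content" && length(target$siblings[[i]]) &&
                   stats::runif(1) < pr$morpheme_rate) {
          w <- sample(target$siblings[[i]], 1L)
        }
        if (stats::runif(1) < pr$typo_rate) w <- typo1(w)
        out <- c(out, w)
      }
    }
    if (stats::runif(1) < pr$content_add_rate) {
      out <- c(out, sample(decoy_words, 1L))
    }
    if (stats::runif(1) < pr$function_add_rate) {
      out <- c(out, sample(funs, 1L))
    }
  }
  paste(out, collapse = " ")
}

# one random single-character edit (substitution, insertion, or deletion)
typo1 <- function(word) {
  ch <- strsplit(word, "")[[1L]]
  n <- length(ch)
  op <- sample(if (n > 1L) 1:3 else 1:2, 1L)
  if (op == 1L) { # substitute
    i <- sample.int(n, 1L)
    ch[i] <- sample(setdiff(letters, ch[i]), 1L)
  } else if (op == 2L) { # insert
    i <- sample.int(n + 1L, 1L)
    ch <- append(ch, sample(letters, 1L), after = i - 1L)
  } else { # delete
    ch <- ch[-sample.int(n, 1L)]
  }
  paste(ch, collapse = "")
}

#' Simulate a full cohort
#'
#' Generates materials, then a trial table covering every subject by
#' condition by sentence, with an independent RNG substream per subject.
#' The same master seed always yields the identical table.
#'
#' @param params A `sim_params` data frame covering every group by
#'   condition cell.
#' @param n_per_group Subjects per group.
#' @param design A [session_design()].
#' @param lexicon A `spin_lexicon`.
#' @param seed Master integer seed.
#' @return List with `trials` (data frame: `subject_id`, `group`,
#'   `condition`, `target`, `response`, `masker_id`), `materials`, and
#'   `seed`.
#' @export
simulate_cohort <- function(params, n_per_group,
                            design = session_design(),
                            lexicon = load_lexicon(spinerr_lexicon_path()),
                            seed = 1L) {
  params <- validate_sim_params(params)
  stopifnot(n_per_group >= 1L)
  materials <- generate_materials(design, lexicon, seed = seed)
  set.seed(seed)
  groups <- unique(params$group)
  n_subj <- length(groups) * n_per_group
  subj_seed <- sample.int(.Machine$integer.max, n_subj)
  v <- sim_vocab()
  # intrusions are drawn from the words actually present in the generated
  # masker sentences, so the overlap statistic identifies the intrusion rate
  masker_tok <- unique(unlist(lapply(materials$maskers, tokenize)))
  masker_words <- masker_tok[lexicon_lookup(masker_tok, lexicon)$cls ==
                               "content"]
  siblings <- morph_siblings(lexicon)
  prepared <- lapply(seq_len(nrow(materials$targets)), function(i) {
    prepare_sim_target(materials$targets$text[i], lexicon, siblings)
  })

  rows <- vector("list", n_subj)
  s <- 0L
  for (g in groups) {
    for (i in seq_len(n_per_group)) {
      s <- s + 1L
      set.seed(subj_seed[s])
      subj <- sprintf("%s%03d", tolower(g), i)
      parts <- lapply(design$conditions, function(cond) {
        pr <- params[params$group == g & params$condition == cond, ,
                     drop = FALSE]
        if (nrow(pr) != 1L) {
          stop("params must have exactly one row for ", g, " x ", cond)
        }
        sel <- which(materials$targets$condition == cond)
        resp <- vapply(sel, function(k) {
          simulate_response(prepared[[k]], pr, lexicon,
                            masker_words, v$decoys)
        }, "")
        data.frame(subject_id = subj, group = g, condition = cond,
                   target = materials$targets$text[sel],
                   response = resp,
                   masker_id = if (cond == "1T") "talker1" else
                     NA_character_,
                   stringsAsFactors = FALSE)
      })
      rows[[s]] <- do.call(rbind, parts)
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = trials, materials = materials, seed = seed)
}
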