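test_that("keywords are scored exactly, position-free, consumed once", {
  lex <- fixture_lexicon()
  tt <- parse_target("The BUCKETS HOLD WATER", lex)
  rt <- tag_tokens(tokenize("the bucket hold water"), lex)
  expect_equal(score_keywords(tt, rt), c(FALSE, TRUE, TRUE))

  # identity
  rt2 <- tag_tokens(tokenize("the buckets hold water"), lex)
  expect_equal(score_keywords(tt, rt2), c(TRUE, TRUE, TRUE))

  # duplicated keywords consume response tokens one-for-one
  tt3 <- parse_target("the DOG saw the DOG", lex)
  rt3 <- tag_tokens("dog", lex)
  expect_equal(score_keywords(tt3, rt3), c(TRUE, FALSE))
})

test_that("keyword scoring ignores word order and function insertions", {
  lex <- fixture_lexicon()
  tt <- parse_target("The BUCKETS HOLD WATER", lex)
  set.seed(31)
  base <- tokenize("the buckets hold water")
  for (rep in 1:10) {
    shuffled <- sample(base)
    extra <- append(shuffled, sample(c("a", "his", "to"), 1),
                    after = sample(0:length(shuffled), 1))
    rt <- tag_tokens(extra, lex)
    expect_equal(score_keywords(tt, rt), c(TRUE, TRUE, TRUE))
  }
})

test_that("DNH classification follows root-level content matching", {
  lex <- fixture_lexicon()
  tgt <- parse_target("the DAUGHTER SET the TABLE", lex)

  expect_equal(classify_dnh(parse_target("he BROKE his LEG", lex),
                            tag_tokens(character(0), lex)),
               "dnh_nothing")
  expect_equal(classify_dnh(tgt, tag_tokens(tokenize("can go very fast"),
                                            lex)),
               "dnh_incorrect")
  # root-level: "daughters" matches root "daughter"
  expect_equal(classify_dnh(tgt, tag_tokens(tokenize("the daughters sat"),
                                            lex)),
               "none")
  # be-forms are not content: a response of only "is" transcribes nothing
  expect_equal(classify_dnh(parse_target("a MAN is TURNING the FAUCET",
                                         lex),
                            tag_tokens("is", lex)),
               "dnh_nothing")
  # function words only -> still nothing transcribed
  expect_equal(classify_dnh(tgt, tag_tokens(tokenize("the the a"), lex)),
               "dnh_nothing")
})

test_that("masker overlap counts content roots in the inventory", {
  lex <- fixture_lexicon()
  inv <- c("go", "fast", "pie")
  rt <- tag_tokens(tokenize("go fast"), lex)
  expect_equal(masker_overlap(rt, inv), list(matched = 2L, total = 2L))

  rt <- tag_tokens("unicorn", lex)
  expect_equal(masker_overlap(rt, inv), list(matched = 0L, total = 1L))

  rt <- tag_tokens(tokenize("go unicorn"), lex)
  expect_equal(masker_overlap(rt, inv), list(matched = 1L, total = 2L))

  # contract: only DNH-Incorrect trials in the 1T condition
  expect_error(masker_overlap(rt, inv, dnh_status = "none"),
               "DNH-Incorrect")
  expect_error(masker_overlap(rt, inv, condition = "SSN"), "1T")
})

test_that("each canonical worked example yields exactly its error type", {
  lex <- fixture_lexicon()
  ex <- worked_examples()
  expected <- worked_expected()
  maskers <- read_maskers(system.file("extdata",
                                      "maskers_1T_synthetic.txt",
                                      package = "spinerr"))
  inv <- masker_root_inventory(maskers, lex)
  for (i in seq_len(nrow(ex))) {
    ts <- score_trial(ex$target[i], ex$response[i], lex,
                      condition = "1T", masker_roots = inv)
    lab <- ex$label[i]
    if (lab == "dnh_nothing") {
      expect_equal(ts$dnh_status, "dnh_nothing", info = lab)
      expect_true(all(!ts$keyword_correct), info = lab)
      expect_true(is.na(ts$content_sub) && is.na(ts$morpheme_errors),
                  info = lab)
    } else if (lab == "dnh_incorrect") {
      expect_equal(ts$dnh_status, "dnh_incorrect", info = lab)
      expect_true(is.na(ts$content_sub), info = lab)
      # the response is masker material: full overlap
      expect_equal(ts$masker_matched, ts$masker_total, info = lab)
      expect_gt(ts$masker_total, 0L)
    } else {
      expect_equal(ts$dnh_status, "none", info = lab)
      expect_equal(error_profile(ts), expected[[lab]], info = lab)
    }
  }
})

test_that("an identical response scores perfectly everywhere", {
  lex <- fixture_lexicon()
  ts <- score_trial("the DAUGHTER SET the TABLE",
                    "the daughter set the table", lex)
  expect_true(all(ts$keyword_correct))
  expect_equal(ts$dnh_status, "none")
  expect_equal(unname(error_profile(ts)), rep(0L, 7))
})

test_that("spell correction feeds scoring: typo'd keyword still counts", {
  lex <- fixture_lexicon()
  ts <- score_trial("a MAN is TURNING the FAUCET",
                    "a man is turning the facet", lex)
  expect_true(all(ts$keyword_correct))
  expect_equal(unname(error_profile(ts)), rep(0L, 7))
})

test_that("alignment pair kinds conserve token counts in scored trials", {
  lex <- fixture_lexicon()
  w <- word_weights()
  set.seed(32)
  vocab <- lex$vocabulary
  for (rep in 1:40) {
    tn <- sample(vocab, sample(1:7, 1))
    rn <- sample(vocab, sample(0:7, 1))
    tt <- tag_tokens(tn, lex)
    rt <- tag_tokens(rn, lex)
    a <- align_words(tt, rt, w)
    errs <- score_word_errors(a)
    paired <- sum(a$kind %in% c("match", "partial", "mismatch"))
    om <- sum(a$kind == "response_gap")
    add <- sum(a$kind == "target_gap")
    expect_equal(paired + om, length(tt))
    expect_equal(paired + add, length(rt))
    expect_equal(errs[["content_om"]] + errs[["function_om"]], om)
    expect_equal(errs[["content_add"]] + errs[["function_add"]], add)
  }
})

test_that("a pair is a morpheme error or a substitution, never both", {
  lex <- fixture_lexicon()
  sib <- morph_siblings(lex)
  set.seed(33)
  content <- lex$word[lex$cls == "content"]
  for (rep in 1:40) {
    tn <- sample(content, 4)
    rn <- tn
    # flip one word to a sibling (morpheme) or a fresh word (substitution)
    k <- sample(4, 1)
    flip_sib <- length(sib[[tn[k]]]) > 0 && runif(1) < 0.5
    rn[k] <- if (flip_sib) sample(sib[[tn[k]]], 1) else
      sample(setdiff(content, tn), 1)
    a <- align_words(tag_tokens(tn, lex), tag_tokens(rn, lex))
    errs <- score_word_errors(a)
    morph <- score_morpheme_errors(a)
    if (rn[k] == tn[k]) next
    expect_equal(errs[["content_sub"]] + morph, 1L,
                 info = paste(tn[k], "->", rn[k]))
  }
})

test_that("DNH trials carry no word or morpheme counts end to end", {
  lex <- fixture_lexicon()
  ts <- score_trial("the DAUGHTER SET the TABLE", "", lex)
  expect_equal(ts$dnh_status, "dnh_nothing")
  expect_true(all(is.na(error_profile(ts))))
  ts <- score_trial("the DAUGHTER SET the TABLE", "unicorn galaxy", lex,
                    condition = "SSN")
  expect_equal(ts$dnh_status, "dnh_incorrect")
  expect_true(all(is.na(error_profile(ts))))
  # masker overlap absent outside 1T even with an inventory
  ts <- score_trial("the DAUGHTER SET the TABLE", "unicorn", lex,
                    condition = "SSN", masker_roots = "unicorn")
  expect_true(is.na(ts$masker_matched))
})

test_that("score_trials validates its input table", {
  lex <- fixture_lexicon()
  expect_error(score_trials(data.frame(subject_id = "s"), lex),
               "lacks column")
  expect_error(score_trials(
    data.frame(subject_id = character(0), group = character(0),
               condition = character(0), target = character(0),
               response = character(0)), lex),
    "empty")
})
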