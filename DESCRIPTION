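Package: spinerr
Title: Transcription Error Analysis for Speech-in-Noise Sentence Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores typed listener responses from speech-in-noise sentence
    recognition experiments. Target and response sentences are tokenized,
    tagged as content or function words against a pluggable lexicon, spell
    corrected, and aligned word-by-word with a weighted Needleman-Wunsch
    global alignment that rewards exact and near (Levenshtein distance <= 2)
    word matches. Each trial is then scored for keyword accuracy, whole
    sentence omissions ("did not hear", split into DNH-Nothing and
    DNH-Incorrect), masker-sentence intrusions, and word-level
    (substitution/addition/omission of content and function words) and
    morpheme-level errors. Subject-by-condition summaries, group descriptive
    tables, and a seedable permutation test for group-by-condition
    interactions are included, together with a synthetic listener-response
    generator that emulates BKB-style sentence lists, a competing-talker
    masker inventory, and configurable per-word error processes so the whole
    pipeline can be exercised and calibrated without access to raw
    participant transcripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
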