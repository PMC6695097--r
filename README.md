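# spinerr

Transcription error analysis for speech-in-noise (SPIN) sentence
recognition experiments.

In SPIN testing, listeners hear short BKB-style sentences against an
interfering masker — a competing talker (1T), the same talker
time-reversed (1T_tr), or speech-shaped noise (SSN) — and type what they
heard. Scoring only the designated keywords tells you *whether*
recognition failed; `spinerr` scores the entire typed response to tell
you *how*. It is intended for psycholinguists and audiologists analyzing
typed SPIN transcripts, in particular for separating informational
masking (interference from the competing talker's words) from energetic
masking.

## What it computes

Each target/response pair is tokenized, tagged as content vs function
words against a pluggable lexicon, spell-corrected (out-of-vocabulary
words only), and aligned word-by-word with a weighted Needleman–Wunsch
global alignment:

* word pairing score: **+20** exact match, **+5** partial match
  (character Levenshtein distance ≤ 2), **−5** mismatch; gaps **−5**.

From the alignment and tags, every trial gets:

* **keyword accuracy** — exact matches only, no morphemes added/removed;
* **DNH status** ("did not hear"): *DNH-Nothing* (no content words
  typed) or *DNH-Incorrect* (content words typed, none sharing a root
  with the target);
* **masker overlap** — for DNH-Incorrect trials under the intelligible
  talker, the share of response content words that come from the masker
  sentences;
* **word-level errors** — substitution / addition / omission, split by
  content vs function words (non-DNH trials only);
* **morpheme errors** — aligned content words sharing a root but
  differing in form (*daughter* → *daughters*).

Subject × condition summaries, group mean ± SD tables, and a seedable
permutation test for the group × condition interaction sit on top. A
synthetic listener simulator generates full cohorts (materials +
responses) with configurable error processes, so the whole pipeline is
testable and calibratable without access to raw participant data.

## Worked example

```r
library(spinerr)
lex <- load_lexicon(spinerr_lexicon_path())

score_trial("the DAUGHTER SET the TABLE", "the daughters set the table", lex)
#> <trial_score>
#>  keywords correct: 2 / 3 (FALSE TRUE TRUE)
#>  dnh_status: none
#>  word errors: content S/A/O 0/0/0, function S/A/O 0/0/0
#>  morpheme errors: 1
#> <word_alignment> score = 85
#>  target  : the daughter set the table
#>  response: the daughters set the table
#>  kinds   : match partl match match match
```

The alignment pairs *daughter*/*daughters* as a partial match (score
4 × 20 + 5 = 85), the roots agree, and the trial scores one morpheme
error, no word-level errors, and keywords `FALSE TRUE TRUE` (the
pluralized keyword is wrong by the exact-match rule).

Scoring the packaged example trials end to end:

```r
res <- cmd_score(
  system.file("extdata", "example_trials.tsv", package = "spinerr"),
  out_dir = "out",
  masker_path = system.file("extdata", "maskers_1T_synthetic.txt",
                            package = "spinerr"))
#> condition 1T: 9 trials (1 DNH-Nothing, 1 DNH-Incorrect)
```

Simulating and analyzing a cohort (40 subjects per group, study-emulating
defaults):

```r
sim <- simulate_cohort(default_sim_params(), n_per_group = 40, seed = 7)
sc  <- score_trials(sim$trials, lex,
                    masker_roots = masker_root_inventory(sim$materials$maskers, lex))
su  <- summarize_scores(sc)
subset(group_table(su), metric == "p_dnh_incorrect" & condition == "1T")
#>      group condition          metric  n      mean         sd
#> 13 control        1T p_dnh_incorrect 40 0.1375000 0.07648110
#> 14     MDD        1T p_dnh_incorrect 40 0.2453125 0.10721890

permutation_interaction_test(su, "p_dnh_incorrect", n_perm = 1000, seed = 3)$p
#> [1] 0.000999001
```

The simulated clinical group shows the planted 1T-specific excess of
DNH-Incorrect errors (≈ 0.25 vs ≈ 0.14 of 16 sentences), and the
permutation test on the 1T-vs-rest contrast detects it at the add-one
floor for 1,000 permutations.

A thin command-line wrapper over the same functions is installed at
`inst/cli/spinerr.R` with `score`, `simulate`, and `summarize`
subcommands.

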