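---
title: "Scoring transcription errors in speech-in-noise sentence recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring transcription errors in speech-in-noise sentence recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a speech-perception-in-noise (SPIN) experiment, listeners hear short
sentences mixed with an interfering masker — a competing talker (1T), the
same talker played time-reversed (1T_tr), or stationary speech-shaped
noise (SSN) — and type what they heard. The standard outcome is keyword
accuracy: each BKB-style sentence designates 3–4 keywords, and a keyword
is correct only if reproduced exactly, with no morphemes added or
removed.

Keyword accuracy says *whether* recognition failed, not *how*. This
package implements a complementary error analysis of the full typed
response. Its taxonomy separates:

* **whole-sentence omissions** ("did not hear", DNH): the response shares
  no content-word root with the target. *DNH-Nothing* means no content
  words were typed at all; *DNH-Incorrect* means content words were
  typed, but none from the target.
* **masker intrusions**: for DNH-Incorrect responses under an
  intelligible competing talker, the fraction of response content words
  that come from the masker sentences. This is the diagnostic signature
  of informational masking — the listener transcribed the wrong talker.
* **word-level errors** on the remaining trials: substitutions,
  additions, and omissions, attributed separately to content words
  (nouns, verbs, adjectives, adverbs) and function words (closed-class).
* **morpheme-level errors**: aligned content words that share a root but
  differ in surface form (pluralization, tense change).

## The alignment model

Word-level errors require knowing which response word corresponds to
which target word. We use a global (Needleman–Wunsch) alignment over
*words*, maximizing

$$S = \sum_{\text{pairs}} s(t_i, r_j) + g \cdot \#\{\text{gaps}\},$$

with

$$s(t, r) = \begin{cases}
 +20 & t = r\\
 +5 & 0 < \mathrm{lev}(t, r) \le 2\\
 -5 & \text{otherwise,}
\end{cases} \qquad g = -5,$$

where $\mathrm{lev}$ is the character-level Levenshtein distance. The
large match reward reflects that two identical words in corresponding
slots are very unlikely by chance in open-set sentence material; the
partial-match reward keeps morphologically or typographically perturbed
words aligned with their source rather than gapped; mismatches and gaps
cost equally. All four weights and the partial-match distance bound are
configurable (`word_weights()`), but the defaults above are the
reference configuration and all downstream counts assume integer scores.

Ties in the dynamic-programming traceback are broken deterministically:
a word pairing is preferred to a gap in the target, which is preferred
to a gap in the response. Among equal-scoring alignments this maximizes
the number of word pairings, which stabilizes the error counts.
Alignment operates on normalized forms (case-folded, edge punctuation
stripped), after spell correction.

## The per-trial pipeline

1. **Tokenize** both sentences: whitespace split, strip edge punctuation
   (`.,!?;:"'()`), case-fold, drop empty pieces. Hyphenated words stay
   whole; numerals count as content words. Typed responses are informal,
   so the simplest reproducible rule is used.
2. **Tag** each word against a lexicon TSV
   (`word<TAB>class<TAB>root[<TAB>frequency]`) as `content`, `function`,
   or `be_form`. Words missing from the lexicon default to `content`
   with the word as its own root: unknown words are most often
   misspelled content words, and the spell corrector runs next. A fixed
   closed list of forms of "to be" is always tagged `be_form`,
   independently of the lexicon.
3. **Spell-correct** out-of-vocabulary response words: candidates are
   lexicon words at edit distance 1, then 2, ordered by corpus frequency
   (descending) then lexicographically; the first candidate equal to a
   content word of the target replaces the token. In-vocabulary words
   are never replaced, so real-word confusions such as homophones remain
   errors. The deterministic candidate ordering replaces the opaque
   "first suggestion" of desktop spellcheckers.
4. **Score keywords**: exact norm matches, position-independent, each
   response token consumable once. Morphological variants are wrong.
5. **Classify DNH** at root level: if no response content root matches a
   target content root (be-forms excluded), the trial is DNH-Nothing
   (no content words at all) or DNH-Incorrect. DNH trials are excluded
   from the word- and morpheme-level counts; DNH-Incorrect trials in the
   1T condition are compared with the masker inventory.
6. **Align and count**: response-side gaps are omissions and target-side
   gaps are additions, attributed to the word's class (be-forms pool
   with function words); non-identical function pairs are function
   substitutions; content pairs with different roots are content
   substitutions, and with equal roots morpheme errors — never both.
   Cross-class pairs are attributed to the *target* word's class, since
   the taxonomy counts errors against the target sentence.

Design points the taxonomy leaves open, and the choices made here: the
masker comparison uses the full masker inventory of the condition's
talker rather than the trial's 50-second excerpt (configurable only in
the sense that any sentence file can be supplied); masker matching is at
root level for symmetry with the DNH rule, with a `surface` option;
function-word substitution requires exact inequality (a partial match
between two different function words is still a substitution); all
matching is case-insensitive.

## Aggregation and inference

Per subject × condition: keyword accuracy pools keywords; DNH
proportions are over all trials of the cell (16 in the reference
design); error means are per *non-DNH* sentence, pooling substitution +
addition + omission within content and function classes. Cells with no
non-DNH trial propagate `NA`, never zero. Masker overlap pools matched /
total content words over the subject's DNH-Incorrect 1T trials. Group
tables report subject-level means and sample SDs (n − 1), so subjects —
not trials — are the unit of analysis.

The upstream literature fits mixed-effects models to these summaries;
those fits are standard and deliberately out of scope here. As a
self-contained inferential surface the package provides a permutation
test for the group × condition interaction: each subject is reduced to
the within-subject contrast (focal condition minus the mean of the
others), the statistic is the group difference of these contrasts, and
group labels are permuted across subjects. The p-value uses the add-one
estimator $p = (1 + \#\{|S^\ast| \ge |S|\})/(1 + B)$, which is never
zero and is slightly conservative. Subject summaries export cleanly to
any mixed-model tool for users who want the parametric analysis.

## The synthetic listener

No raw participant transcripts ship with the package; instead a
generative model produces cohorts with the statistical structure the
analysis assumes, so every stage is testable end to end.

**Materials.** Targets are template sentences (`the NOUN VERB the NOUN`,
with an adjective slot on 4-keyword sentences) over a small lexicon;
each 16-sentence list carries exactly 50 uppercase keywords (14 × 3 +
2 × 4). The masker inventory is 30 sentences from a content vocabulary
disjoint from the target vocabulary, and irrelevant-response "decoy"
words are disjoint from both, so the masker-intrusion probability is
identifiable from the overlap statistic. The −5 dB SNR of the reference
design is carried as metadata; no audio is synthesized.

**Responses.** Per trial: with probability `dnh_nothing_rate` the
response is empty; else with probability `dnh_incorrect_rate` it is 2–4
content words drawn from the masker inventory (each with probability
`masker_intrusion_prob`) or the decoy pool; otherwise the target is
copied and perturbed by independent per-word processes — substitution
(root-changing), addition, omission (content and function rates
separate), morpheme flips (a lexicon sibling sharing the root; words
without siblings, e.g. the adjectives, are ineligible), and one-edit
typos. `keyword_hit_rate` is defined as the cell's target *marginal*
keyword accuracy; the generator converts it internally to a conditional
per-keyword knockout probability that accounts for the cell's DNH and
word-error rates. The default parameter table (`default_sim_params()`)
emulates the group × condition pattern reported for a clinical MDD
cohort: 1T keyword accuracy 65.2% vs 75.0%, a DNH-Incorrect excess of
26.5% vs 16.3% confined to the 1T condition, ~70% masker intrusion, and
morpheme errors highest under SSN. Word-level rates are not reported in
that literature at per-word resolution; the defaults (2–8% per word) are
chosen to give the plausible one-ish error per sentence.

**What the simulator is not.** Error processes are independent per word,
with no length or position coupling, no acoustic or phonetic confusion
structure, no semantically plausible substitutions, and typos are single
edits. Passing closed-loop tests therefore demonstrates that the
pipeline recovers the processes it defines, on materials it can tag
perfectly — not that the taxonomy captures everything human listeners
do, nor how the pipeline behaves with an impoverished lexicon.

## Numerical and testing choices

* Integer scores throughout the alignment; `utils::adist` supplies the
  Levenshtein distances, cross-checked in the tests against an
  independent recursion.
* Degenerate inputs: empty responses align to all-gaps (score
  $n \cdot g$); empty lexicons are legal; a response consisting only of
  function words or be-forms is DNH-Nothing.
* Identical token sequences short-circuit to the all-match diagonal,
  which is provably optimal since the match reward is the per-pair
  maximum and gaps are non-positive.
* Test problem sizes: alignment optimality is verified against a
  brute-force oracle on 1,000 random pairs (length ≤ 6) plus full
  alignment enumeration on shorter pairs; closed-loop recovery uses 20
  subjects × 16 trials per process (with the exact conditional
  Binomial law for processes whose extremes convert a trial to DNH);
  power and calibration of the permutation test use 100 planted-effect
  cohorts of 40 subjects per group and 200 null cohorts of 20 per
  group. These sizes give stable Monte-Carlo behavior while keeping the
  default test run short.
* All randomness flows from explicit seeds; cohorts use per-subject
  substreams drawn from the master seed, so any subject's data can be
  regenerated.

## Known limitations

The lexicon-lookup tagger is not a statistical POS tagger: words used in
an unlisted sense are tagged by their listed class, and out-of-lexicon
words default to content. Spell correction considers only edit distance
≤ 2 and only corrections toward target content words, by design. The
permutation test assumes exchangeability of subjects under the null and
tests a single planned contrast; it is a pragmatic substitute for, not
an equivalent of, a mixed-effects likelihood analysis. Masker overlap is
undefined for subjects without DNH-Incorrect 1T trials and is reported
descriptively only.
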