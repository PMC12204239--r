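---
title: "Lexical trajectories in crisis chat conversations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexical trajectories in crisis chat conversations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chatlex)
```

## The problem

Crisis helplines want to know whether a help-seeker's state changes over
the course of a single chat conversation, without burdening anyone with
questionnaires. A transparent way to approximate this is lexicon-based
scoring: count how often the help-seeker's messages use terms from
categories that stand for mental-state constructs (negative emotion,
suffering, distress, suicidality, ...) and track those scores across the
conversation. `chatlex` implements that analysis end to end for two-party
chat transcripts, together with a synthetic corpus generator that makes
the whole pipeline testable against known ground truth.

Only help-seeker messages are ever scored. Supporter (and automated/bot)
messages are carried through the corpus for completeness but never enter
any token stream; segmentation is likewise defined over help-seeker
messages only, so a conversation's "length" always means the number of
help-seeker messages.

## Scoring model

Each message is lowercased and split into tokens on any character that is
not a letter, digit or apostrophe (so contractions stay whole); URLs,
digit-only tokens and symbols are dropped since they cannot match any
pattern. Tokens are reduced to stems with the original Porter (1980)
suffix-stripping algorithm, implemented in this package and verified in
the test suite against the worked examples published with the algorithm's
definition. Bigrams — adjacent stemmed pairs — are formed strictly within
a message: a phrase split across two chat messages was never adjacent in
the speaker's utterance. Because stemming precedes bigram formation,
"harming myself" and "harm myself" collapse onto the same bigram key.

A lexical category is a set of patterns classified by syntax:

* exact stem — `hurt` matches any token stemming to "hurt";
* prefix wildcard — `suicid*` matches any stemmed token starting with
  "suicid" (capturing *suicide*, *suicidal*, *suicidality*);
* bigram — `harm myself` matches the stemmed pair.

Within a category, bigram patterns match first and consume their two
tokens, so `harm myself` is one occurrence even when `harm*` is also a
member pattern. Categories are matched independently of each other and
may freely share member terms. Two scores are computed per segment: the
raw occurrence count, and the lexical degree score — count divided by the
segment's unigram total, clamped to [0, 1], undefined (`NA`, never 0) for
an empty segment. The unigram total is the denominator because bigrams
are views over the same tokens, not additional ones; the degree score
then reads as "proportion of words in the segment that signal the
category". By convention the four general-emotion categories are compared
on degree scores and the two contextual crisis categories (distress,
suicidality) on counts; both metrics are always computed, the choice is a
report option.

The bundled lexicon is deliberately partial. The two contextual
categories carry their ten most frequent published member terms plus the
`harm myself` bigram; the four general-emotion lists are synthetic
stand-ins seeded from the most frequent member terms of the full
validated vocabularies (which run to roughly 75–130 terms per category
and are not redistributable). Absolute scores computed with these lists
are therefore not comparable to scores from full lexicons; the pipeline
itself is indifferent to lexicon size.

## Segmentation

Two complementary segmentations are computed per conversation of `n`
help-seeker messages:

* **Phases**: three contiguous spans of as-equal-as-possible size
  ("beginning", "middle", "end"). Remainders go to the earliest phases
  (`n = 3q+1` gives sizes `q+1, q, q`), a deterministic rule chosen
  because conversation openings tend to be verbose; the alternative
  (remainder last) changes nothing downstream beyond single-message
  shifts.
* **Windows**: nine spans of 20% width starting every 10% of the
  conversation, so consecutive windows overlap by half. Boundaries are
  `round(0.1 k n)` with round-half-up (R's `round()` rounds half to
  even, which is not reproducible across conventions); the final window
  is pinned to end at `n`. For any `n ≥ 10` all nine windows are
  nonempty, the windows cover every message, and no interior message
  falls into more than two windows — properties the suite verifies
  exhaustively for `n` up to 400.

The eligibility filter (at least 10 help-seeker messages, matching the
windowing floor) and the bot-message drop are applied before scoring.

## Statistics

* **Correlations.** Pearson correlations of per-conversation
  whole-conversation counts between categories, two-sided p from the t
  distribution on `n − 2` df. Zero-variance categories yield `NA` and a
  flag, never a fabricated 0.
* **Phase comparisons.** One-way ANOVA treating the `3n` phase values as
  three independent groups — this matches the degrees of freedom
  `(2, 3n − 3)` reported for this design; a repeated-measures variant is
  out of scope. Post hoc Student two-sample t tests (pooled variance)
  compare the three phase pairs. Because no multiplicity correction is
  stated for this design, the uncorrected p is reported alongside a
  Bonferroni-adjusted column. Cohen's d uses the pooled SD for equal
  group sizes, `d = (m1 − m2) / sqrt((s1² + s2²)/2)`, signed so that a
  decline over the conversation is positive.
* **Trends.** For each category, the mean occurrence count per window
  ordinal across conversations, then OLS of those nine means on the
  ordinal 1–9. The slope is change per window step; R² equals the
  squared Pearson correlation of ordinal and mean. Constant means return
  slope 0 and R² 0 rather than an undefined ratio.

## The synthetic generator

`generate_corpus()` emulates the structure of a filtered crisis-chat
corpus:

* Help-seeker message counts follow a negative binomial truncated to
  [10, 382]. The untruncated parameters are calibrated numerically (at
  config construction) so the *truncated* distribution hits the target
  mean 30.5 and SD 20.6 — the descriptive statistics of the population
  the generator emulates.
* Tokens per message are Poisson with mean 12 (floor 1), a realistic
  chat-message length once punctuation is stripped.
* Each help-seeker token is a category-term emission with probability
  `rate_c(u)` interpolated linearly between a start and end rate over
  normalized position `u = index/(n−1)`, else a filler pseudo-word that
  matches nothing. Default rates echo the phase-level magnitudes
  reported for real crisis chats (for example distress 0.034 → 0.010,
  optimism flat at 0.007); they were fixed once from those published
  phase means and are not tuning knobs.
* Emitted surfaces are drawn from the category's pattern pool including
  inflected variants (*-s*, *-ed*, *-ing*) that only survive into the
  pool if they genuinely match the pattern after stemming — so the
  generator exercises the stemmer and wildcard machinery by
  construction.
* Supporter messages are interleaved (probability 0.8 after each
  help-seeker message) and built entirely from filler vocabulary, which
  lets the suite verify the help-seeker-only contract end to end: a test
  rewrites every supporter message to be saturated with category terms
  and asserts bit-identical results.

The generator returns emission-based ground truth: expected window mean
counts given the realized lengths, and their OLS slope.

**What the generator does not emulate.** Real chat language — topic
structure, negation, sarcasm, misspellings, emoji, code-switching — is
absent; filler tokens are pseudo-words, so passing tests demonstrate that
the measurement pipeline is correct, not that the lexicons are valid
instruments for real text. One real-data feature the generator *does*
reproduce is member-term overlap between categories, and it matters:
because declining categories emit terms that other categories also list
(e.g. "feel" in several), a flat-emission category scored with the
bundled overlapping lexicon shows an apparent decline. This cross-talk is
a property of overlapping lexicons, not a bug; consequently the
null-calibration (type-I error) and sign-recovery properties are tested
with dedicated disjoint-vocabulary lexicons, where the null is actually
true. For the same reason the null check uses degree scores: under the
generative null, phase degree scores are independent across phases,
whereas raw counts correlate through conversation length and make the
independent-groups F test conservative.

## Numerical and design choices

* Round-half-up for window boundaries; division-exact arithmetic
  (`k·n/10`) avoids float jitter at exact halves.
* `top_terms()` breaks frequency ties lexicographically by key, making
  reports deterministic.
* Per-conversation SDs use the sample (n−1) denominator.
* An exact-stem pattern whose key equals a wildcard key of the same
  category is dropped as redundant (the wildcard subsumes it), keeping
  pattern keys unique within a category.
* Degree scores for empty segments are `NA` and excluded (with a
  warning) from phase ANOVA and window means rather than imputed.
* Corpus-level scoring is vectorized (flattened token vector, prefix
  sums over message spans) but provably equivalent to per-segment
  matching, which the suite checks segment by segment.
* Problem sizes in the test suite — 200 replicate corpora of 40
  conversations for the null calibration, one 500-conversation corpus
  for sign recovery, property loops of 100–200 random streams — were
  chosen to give stable binomial bands (99% band [3, 18] rejections out
  of 200 at α = .05) while keeping the default test run quick.

## Known limitations

Lexicon scoring is context-agnostic: "suicide" counts identically whether
the help-seeker discusses it abstractly or expresses intent, and
negation, sarcasm and misspellings are invisible. The bundled lexicons
are partial stand-ins, suitable for pipeline validation rather than
substantive inference. The ANOVA treats phases as independent groups to
match the published design even though phase values from one conversation
are correlated; with overlapping categories the post hoc tests inherit
whatever cross-talk the lexicons carry. Trend slopes are per window step
(1–9); rescale by 10% of conversation length per step if a
per-conversation-fraction slope is wanted.
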