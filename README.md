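# chatlex

Lexicon-based trajectory analysis of crisis online-chat conversations.

Crisis helplines have almost no unobtrusive way to tell whether a
help-seeker's state changes during a single chat. `chatlex` implements a
transparent, fully auditable approach: score only the *help-seeker's*
messages against lexical categories — general-emotion categories
(negative emotion, positive emotion, suffering, optimism, scored by
lexical degree, i.e. the proportion of words matching the category) and
crisis-specific ones (distress, suicidality, scored by raw occurrence
counts) — and track those scores across the conversation. It is aimed at
researchers in computational mental health and service-evaluation teams
who need the measurement pipeline, the statistics and a synthetic
test-bed in one tested package.

## What it computes

For each conversation with at least 10 help-seeker messages:

* **Preprocessing** — lowercasing; tokenization that keeps contractions;
  original Porter (1980) stemming (implemented and oracle-tested in the
  package); within-message bigrams, so phrase patterns like
  `harm myself` match as single terms.
* **Matching** — exact-stem, prefix-wildcard (`suicid*` captures
  *suicide / suicidal / suicidality* after stemming) and bigram
  patterns; bigrams consume their tokens first so nothing double-counts.
* **Segmentation** — three equal phases (beginning / middle / end) and
  nine overlapping windows (20% width, 50% step) over help-seeker
  messages.
* **Statistics** — Pearson correlations between categories; per-category
  one-way ANOVA across phases, `F(2, 3n−3)`, with post hoc pooled t
  tests and Cohen's `d = (m1 − m2) / sqrt((s1² + s2²)/2)` (positive =
  decline); OLS trend `mean_k = a + b·k` over window ordinals `k = 1..9`
  with `R²`.
* **Synthetic corpora** — a generator with negative-binomial
  conversation lengths (truncated to [10, 382], calibrated to mean 30.5
  / SD 20.6) and per-token category-term emission rates that decline (or
  stay flat) over conversation position, returning ground truth for
  parameter-recovery checks.

## Worked example

```r
library(chatlex)

cfg <- synth_config(n_conversations = 200, seed = 42)
sim <- generate_corpus(cfg)           # corpus + ground truth
fit <- lexical_trajectory(sim$corpus) # filter -> score -> stats
fit
#> Lexical trajectory fit: 200 conversations, 6 categories
#>           category d_beginning_end trend_slope r_squared
#> 1 negative_emotion            0.73     -0.1409     0.960
#> 2 positive_emotion            0.30     -0.0420     0.828
#> 3        suffering            0.83     -0.1625     0.996
#> 4         optimism            0.14     -0.0186     0.276
#> 5         distress            0.74     -0.2708     0.991
#> 6      suicidality            0.65     -0.1363     0.971
```

All negatively framed categories decline over the synthetic
conversations (negative slopes, large beginning-to-end effect sizes),
while flat-emission optimism shows only a small drift — picked up from
terms it shares with declining categories, a documented property of
overlapping lexicons. Drill into one category:

```r
fit$phases$distress
#> One-way ANOVA across conversation phases: distress (count)
#>   F(2, 597) = 27.66, p 3.25e-12
#>      beginning middle    end
#> mean    6.5250 4.7000 3.2750
#> sd      5.4246 4.3606 3.0208
#>              pair    t            p p_bonferroni    d
#>  beginning-middle 3.71 2.383151e-04 7.149454e-04 0.37
#>        middle-end 3.80 1.679910e-04 5.039731e-04 0.38
#>     beginning-end 7.40 8.029764e-13 2.408929e-12 0.74
```

Mean distress-term occurrences fall from 6.5 per conversation-third at
the beginning to 3.3 at the end — a standardized reduction of d = 0.74.
`coef(fit)` returns the slope/intercept/R² matrix, `plot(fit)` draws the
nine window means with fitted trend lines, `top_terms(fit$scores,
"suicidality")` ranks the matched member terms, and
`recovery_report(sim$corpus, sim$truth, fit)` compares the fitted slopes
against the generator's ground truth. Real transcripts enter through
`read_transcripts()` (JSON Lines or CSV; one message per record with
`conversation_id`, `index`, `role`, `timestamp`, `text`), and
`run_pipeline()` writes the full set of CSV artifacts plus a
reproducibility manifest.

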