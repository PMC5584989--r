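---
title: "Measuring readability trends in scientific abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring readability trends in scientific abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scireadability)
```

## The problem

Readability formulas estimate how hard a text is to read from surface
features: sentence length, word length in syllables, and vocabulary
familiarity. Applied to hundreds of thousands of scientific abstracts they
reveal a systematic drift — later abstracts use longer sentences, more
polysyllabic words, and a larger share of vocabulary unfamiliar to general
readers — and the growth of a field-neutral scientific jargon accounts for
much of it. This package implements that analysis as a tested pipeline:
preprocessing, scoring, word-list derivation, and hierarchical trend
modelling, exercised end to end on a synthetic corpus whose true trends are
known in closed form.

## Scores and their components

For a document with `words` word tokens, `sentences` sentences and
`syllables` total syllables,

* Flesch Reading Ease: `FRE = 206.835 − 1.015 (words/sentences) − 84.6
  (syllables/words)`; lower is harder. Scores of 0–30 correspond roughly to
  college-graduate reading level.
* New Dale-Chall: `NDC = 0.1579 · pct_difficult + 0.0496
  (words/sentences)`, plus a constant 3.6365 when the percentage of
  difficult words exceeds 5. A token is *difficult* when absent from a
  fixed common-word list of 2,949 familiar words. Higher is harder. The
  score is computed on the entire text rather than a 100-word sample.

The piecewise NDC condition is applied as *strictly greater than 5%*, the
standard Dale-Chall convention; sources sometimes typeset the two branches
ambiguously, so the boundary case (`pct_difficult = 5`) is pinned by an
explicit test. Difficult-word counting is token-level (every occurrence
counts), the standard practice when whole texts are scored.

A *word* is any token that carries at least one syllable; sentence counts
are the number of terminal periods after cleaning; sentences with a single
word are ignored, so every scoreable document has `words_per_sentence >= 2`.

### Syllable counting

Three steps, in order:

1. a token containing none of a/e/i/o/u/y is not a word (0 syllables);
2. if the token is in the syllable dictionary, use its count, taking the
   *largest* alternative when several are listed;
3. otherwise count maximal runs of consecutive a/e/i/o/u — so adjacent
   vowels ("ea", "uie") count once, which is the simplest consistent
   reading of "excluding diphthongs" — and add one syllable for a terminal
   'y'.

The bundled dictionary (`syllable_dict_synthetic.tsv`, ~500 entries) is a
hand-curated exception table rather than a full pronouncing dictionary: it
covers silent-final-e words ("make"), words whose only vowel letter is an
internal 'y' ("rhythm", which step 3 would otherwise count as 0),
multi-count words ("fire 1,2"), and common irregulars. Because step 3 is
deterministic, per-word counts are reproducible; they will not always equal
a phonetician's count (step 3 gives "microscope" 4), and no parity with any
particular pronouncing dictionary is claimed. Words that pass step 1 but
count 0 in step 3 simply do not contribute to word or syllable totals,
matching the rule that word counts include only tokens with at least one
syllable.

## Preprocessing

Raw abstracts carry numbers, abbreviations, parenthetical statistics and
boilerplate that would corrupt sentence and syllable counts. `clean_text()`
applies ten heuristic rules in a documented order (abbreviation removal,
period-spacing repair, terminal-period insertion, trailing-number removal,
"etc." preservation, single-letter removal except a/A/I, nucleic-acid-token
removal, hyphen splitting, binomial-period resolution, boilerplate
stripping), then a final pass that removes remaining digit tokens and
punctuation other than sentence-ending periods. Segmentation then splits on
periods, lowercases, and drops tokens that cannot carry a syllable and
sentences with fewer than two words.

Design notes:

* The rules are *operational definitions*: published descriptions of such
  cleaning are rarely precise enough to recover exactly, so each rule is a
  documented, toggleable heuristic (`preprocess_rules()`), the boilerplate
  phrase list is an editable resource file, and `preprocess = FALSE`
  reproduces the raw-text sensitivity analysis.
* Sentence segmentation is a deterministic period-splitter rather than an
  external statistical tagger: the cleaning rules already normalise periods
  to sentence boundaries, and determinism buys exact reproducibility.
* A single capital starting a binomial ("E. coli") is protected from the
  single-letter rule until the binomial period is resolved; the lone
  capital then falls to the final single-letter pass, so "E. coli" ends as
  "coli". Sentences that genuinely end in an all-caps abbreviation keep
  their period.
* `clean_text` is idempotent — cleaning cleaned text changes nothing — and
  this is enforced over the whole fixture suite.

## Word lists

`derive_science_common_words()` rebuilds the "science-specific common
words" construction: sample `n_per_stratum` documents from each publication
stratum (decade-like bins, to avoid recency bias), count token frequencies,
drop words on the exclusion list (the common-word list), keep the `k` most
frequent (default `k = 2949`, the length of the common-word list). Ties at
the cut are broken alphabetically so the derivation is deterministic; the
sampled document ids are recorded in a derivation report so they can be
excluded from downstream analysis. `verification_overlap()` measures the
fraction of a derived list found in an independently derived list — the
replication check for the construction.

The general-scientific-jargon list is consumed as a fixture, never derived
automatically: the original was produced by manual rating against four
written guidelines (excluding units and abbreviations, field-specific
words, discovery-driven words, and everyday words), and that judgment step
is out of scope. The bundled `science_jargon_synthetic.txt` is a
hand-curated stand-in.

## Trend models

`yearly_summary()` averages scores per year, excluding years with fewer
than 10 abstracts (default `min_n = 10`). `pearson_trend()` provides
Pearson correlations with Fisher-z 95% confidence intervals; yearly trends
are unweighted (each qualifying year counts once).

`fit_mixed_models()` fits, by maximum likelihood:

* **M0** — score ~ (1 | journal): journal random intercepts only;
* **M1** — score ~ year + (1 | journal): adds the fixed year effect;
* **M2** — score ~ year + (1 + year | journal): adds journal-specific
  random year slopes.

Models are compared by AIC and BIC (differences against the best model).
Fixed-effect tests use Satterthwaite denominator degrees of freedom
(lmerTest); the 95% CI is Wald, `beta ± t(df, 0.975) · se`. The
author-count model is M2 plus `n_authors` as a second fixed effect, run on
the 1–10-author subset and on all complete records; documents lacking
author counts are excluded with a logged count.

Numerical choices:

* **Year centering.** By default year is centered at the corpus midpoint
  before fitting. With raw calendar years (~2000) the random intercept and
  slope are almost perfectly correlated and optimizers converge poorly;
  centering is an exact affine reparameterisation — year slopes, AIC and
  BIC are unchanged (enforced by test) — so the default favours
  conditioning. `center_year = FALSE` is available.
* **Optimizer.** `bobyqa`, which converges cleanly on corpora where the
  default optimizer emits spurious gradient warnings at identical
  estimates.
* **Degenerate inputs.** A single-journal corpus cannot support journal
  random effects: the ladder falls back to an ordinary least-squares year
  trend, flagged `degenerate`, with residual degrees of freedom — the
  documented fallback when Satterthwaite is unavailable. Singular M2 fits
  (random-slope variance collapsing to zero) are returned with a warning
  rather than suppressed.

`journal_slopes()` reports each journal's total slope (fixed effect plus
BLUP deviation); `summarize_field_slopes()` averages them within research
fields, with journals mapped to several fields contributing to each, and a
single-journal field reporting `NA` standard error.

## The synthetic corpus generator

`generate_corpus()` emulates exactly the structure the models assume. Each
document draws a journal (uniform), a year (uniform over the range), an
author count (`1 + Poisson(author_lambda − 1)`, so every article has an
author), and a latent *jargon weight*

```
p = clamp(base + slope·(year − start) + journal_intercept
          + journal_slope·(year − start) + author_effect·(n_authors − mean))
```

Sentences (count `4 + Poisson(mean − 4)`, length `2 + Poisson(mu(year) −
2)`, so segmentation never drops a sentence) are filled with words drawn
from a multi-syllable jargon vocabulary with probability `p`, otherwise
from a monosyllabic easy vocabulary drawn from the common-word list.
Because the vocabularies are sampled with flat weights, every component's
population slope is an exact mixture: the percentage of difficult words
moves at `100·(d_j − d_e)·slope`, syllables-per-word at `(s_j − s_e)·slope`,
and FRE and NDC follow by linearity (`expected_slopes()`). A Zipf-weighting
option (`zipf_s > 0`) gives vocabularies the rank-frequency structure of
real text; it is used for word-ranking replication properties, where flat
weights would make all jargon words exchangeable and a top-k list
meaningless, and deliberately *not* for slope recovery, where flat weights
keep the ground truth exact.

Default conditions (chosen once): 5,000 abstracts, 20 journals, years
1976–2015, 7 sentences per abstract of ~12 words growing 0.02 words/yr,
jargon weight 0.25 at the start year, journal intercept SD 0.03 and slope
SD 4×10⁻⁴ (jargon-weight units), mean 4 authors. The jargon-weight slope
and author effect are calibrated from the vocabularies so the implied
population trend is **−0.19 FRE/year** and **−0.24 FRE/author** — the
magnitudes reported for the real 709,577-abstract corpus — so recovery
tests run at a representative effect size. `expected_slopes()` returns the
implied truths; clamp-free configurations keep empirical component slopes
within Monte-Carlo error of them (enforced by test), and configurations
that clamp more than 10% of documents warn.

What the generator does *not* emulate: Zipfian vocabulary within documents
(by default), semantic coherence, structured abstracts, real journals'
unequal sizes and year coverage, secular changes in abstract length, or
text that actually needs cleaning (generated text is already clean, so the
preprocessing rules are exercised by hand-built fixtures, not by the
generator). Passing recovery tests therefore validates the statistical
pipeline on data satisfying the model's assumptions; it does not show the
formulas measure "true" readability of English prose.

## Verification at a glance

The test suite asserts, among others: formula oracles against straight-line
evaluations (tolerance 1e-9, including the 5% NDC boundary); a 60-word
syllable table covering all three steps exactly; one before/after fixture
per cleaning rule plus idempotence; brute-force equality of the word-list
derivation on enumerable corpora with and without exclusions; same-seed
determinism everywhere; and the parameter-recovery properties — across 50
simulated corpora (seeds 1–50, default conditions) the mean recovered M2
year slope within ±20% of truth with ≥85% CI coverage and AIC selecting M2
in ≥90% of corpora; 95% CIs covering zero in ≥90% of 50 null corpora
(2,000 abstracts each, all generated effects zero); and the author effect
recovered on the 1–10 subset without absorbing the year trend (10 corpora).
Problem sizes were chosen so the whole suite runs in minutes on one CPU
while keeping Monte-Carlo error well inside the asserted tolerances.

## Limitations

* Absolute scores depend on the common-word list and syllable dictionary;
  with the bundled synthetic stand-ins they are internally consistent but
  not comparable to scores computed against the genuine NDC list.
* Readability formulas measure surface difficulty only; rhetoric, layout
  and idea complexity are invisible to them.
* The preprocessing rules are heuristics tuned for abstract-like prose;
  exotic notation-heavy text may segment poorly.
* Satterthwaite degrees of freedom depend on the fitting engine; exact df
  parity with other implementations is not claimed (at large n the
  p-values are insensitive to this).
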