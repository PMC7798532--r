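---
title: "Measuring aging narratives across decades: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring aging narratives across decades: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agenarr)
```

## The measurement problem

`agenarr` measures how narratives about older adults evolve across a
diachronic corpus: a collection of texts tagged by year (1810–2019, binned
into 21 decades) and genre (newspaper, magazine, fiction, nonfiction).
The measurement chain is:

1. **Concordance.** Every occurrence of a target synonym for "older adult"
   (e.g. *elderly*, *old people*) is located, with up to four tokens of
   context on each side. Multiword terms are matched longest-first, left to
   right, without overlap, and windows never cross document boundaries.
2. **Collocation with Mutual Information filtering.** Windowed co-occurrence
   counts are converted to an association score,
   $\mathrm{MI} = \log_2 \frac{f_{joint}\, N}{f_{node}\, f_{coll}\, W}$,
   with $W = 8$ for a ±4-token window — the pointwise-MI convention with a
   window-span correction used by the large reference corpora this design
   targets. Per synonym and decade, candidates are ranked by joint
   frequency, truncated to the top 100, and kept only when MI ≥ 3 bits
   ("semantic bonding"). An exclusion list stands in for the human
   relevance check of the original protocol; unrated words are likewise
   excluded at the scoring stage.
3. **Rating.** Retained collocates are scored against multi-rater rating
   lexicons on six dimensions: sentiment (1 = very negative … 5 = very
   positive), status (1–3), warmth (1–5), competence (1–5), and the binary
   medicalization and ostracism. Consensus is the mean over available
   raters; inter-rater reliability is Cronbach's alpha with a Feldt
   F-interval.
4. **CANS.** For each synonym and decade, the `f_joint`-weighted mean
   consensus sentiment; decades aggregate synonym means weighted by how
   often each synonym occurred:
   $\mathrm{CANS}_d = \sum_s w_{s,d}\,\bar{x}_{s,d} \big/ \sum_s w_{s,d}$.
   Trends are ordinary least squares on the decade index (0 = 1810s) with
   linear, quadratic and cubic fits reported separately, each headlined by
   its highest-order coefficient.
5. **Topics.** Per genre × century stratum, the retained window tokens of
   each source document form a bag; LDA is fitted by collapsed Gibbs
   sampling.
6. **Predictors.** A synonym × decade table regresses the sentiment score
   on the five sociological dimensions in a linear mixed model with a
   random intercept per decade (REML, Wald tests).

A note on scale direction: the rating convention here puts 1 at *very
negative* and 5 at *very positive*, consistent with canonical example
ratings (*abuse*, *frail* → 1; *apartment*, *armchair* → 3;
*affectionate*, *wise* → 5) and with the interpretation that a declining
CANS means increasingly negative narratives.

## Interpretation choices that were genuinely open

Several quantities are underdetermined by the protocol the package
implements; the choices below are recorded as package decisions, each with
an escape hatch where reasonable.

- **Collocate weighting within a synonym-decade mean.** The protocol asks
  for "a mean score" per synonym per decade without saying whether
  collocates are weighted. The default weights by `f_joint`
  (frequency-faithful: a collocate seen 30 times matters more than one
  seen once); `weight = "none"` gives the unweighted reading.
- **Filter order.** Ranking/truncation to the top 100 happens before the
  MI threshold and exclusions, mirroring the order in which the inclusion
  criteria are stated. Ties in joint frequency break by MI, then
  lexicographically, so filtering is deterministic.
- **Period conventions.** "1800s" means the 1810s–1890s (nine decades) and
  "1900s" the 1900s–1990s (ten), the only split consistent with the
  reference proportions 6/9 = 66.7% and 3/10 = 30%. Topic strata use
  19th century = 1810–1899, 20th = 1900–2009.
- **Topic-model document unit.** LDA is fitted to per-source-document bags
  of retained collocates rather than to century-pooled collocate lists;
  windows alone are too short for stable inference, and per-document bags
  preserve the mixture structure LDA assumes.
- **Mixed-model unit of analysis.** A per-decade-only outcome (21 rows)
  cannot identify five fixed effects plus a decade random intercept; the
  synonym × decade level is the only internally consistent reading, and it
  is what `build_predictor_table()` produces. Rows can optionally be
  weighted by synonym frequency (`weighted = TRUE`); default unweighted.
- **Surface forms.** All counting is on surface forms; no lemmatizer is
  bundled and none is applied.

## What the synthetic generator emulates

Licensed corpora and human raters cannot ship with a package, so
`generator_spec()` + `generate_corpus()` produce corpora whose *analytic
ground truth is known exactly*, and every downstream stage is validated
against that truth.

The mechanism: three disjoint sentiment strata (true values 1, 3, 5) with
a fixed neutral mass `p_neutral` and decade-varying negative/positive
masses solved so that the expected sentiment of a rated flanking collocate
in decade $d$ is exactly $b_0 + s\,d$. This is the simplest design whose
expected CANS is exactly affine, which is what makes slope recovery a
sharp test. Planted topic words are drawn *inside* the neutral mass (true
sentiment 3, a configurable share of neutral draws), so topic structure
never perturbs the expected score; they appear only in documents of their
(genre, century) stratum. Background filler words surround the mentions
and are deliberately absent from the rating lexicons: they exercise the
"unrated words are excluded" path, the package's mechanization of the
human relevance criterion.

Default parameters and why:

- `b0 = 3.08`, `drift = -0.0068`: the reference study's intercept and
  linear slope, so the default corpus embodies the study conditions at
  desk scale. Recovery experiments use a steeper `-0.05` so the planted
  signal is identifiable in small corpora.
- `gap_tokens = 80` background tokens between mentions. This sets the
  decade token total `N` high enough that genuine stratum collocates sit
  comfortably above the 3-bit MI threshold (their marginal frequency is
  confined to windows), while background words — frequent everywhere —
  fall well below it. With smaller `N` the MI filter starts clipping
  frequent stratum words, which selectively removes whichever sentiment
  stratum dominates a decade and attenuates the planted slope.
- `rater_noise_sd = 0.24` with two raters. Rater reports are
  `round(truth + noise)` clipped to range, so this calibrates planted
  inter-rater reliability to Cronbach's alpha ≈ .984 at the default
  lexicon composition — the reliability regime the measurement protocol
  reports. Setting it to 0 gives literally perfect raters (alpha = 1).
- 21 decades × 4 genres × 2 documents × 6 mentions: the smallest layout
  that exercises every decade and stratum while keeping a full pipeline
  run in single-digit seconds, so that multi-hundred-replicate recovery
  studies stay inside ordinary desk budgets.

What the generator does *not* emulate: real English syntax and
morphology, genre register, changes in corpus size across decades,
polysemy of the target terms, and rater biases that correlate across
words. Passing recovery tests therefore demonstrates that the pipeline
measures what it claims *given* the inclusion criteria — not that the
inclusion criteria themselves capture human narrative judgments.

Two focused recovery instruments bypass the corpus: `simulate_topic_corpus()`
plants disjoint-vocabulary topics directly as bags (recovery target for
the Gibbs sampler), and `simulate_predictor_table()` plants the five fixed
effects at the row level of the mixed model, so the true coefficients are
exact. The defaults for the planted coefficients (status 0.68, warmth
0.37, competence 0.44, medicalization −1.26, ostracism −0.79) are the
reference study's reported estimates.

## Numerical and degenerate-case policy

- MI of a zero joint count is `-Inf` (never retained); zero marginals are
  an error rather than a silent `NaN`.
- Cronbach's alpha with zero total variance is returned as `NA` with a
  `degenerate` flag — it is undefined, not 1.
- Noiseless trend inputs are interpolated exactly; the fit carries a
  `degenerate` flag and its p-values should not be interpreted.
- REML variance estimates at the zero boundary are reported via the
  `singular` flag; in that case fixed effects coincide with ordinary least
  squares (this is asserted to 1e-6 in the tests). Collinear or constant
  predictors abort with the offending columns named.
- The Gibbs sampler uses R's RNG: a fixed seed reproduces topic
  assignments exactly. LDA defaults are the classical collapsed-Gibbs
  settings `alpha = 50/K`, `eta = 0.01`, 1000 sweeps; per-stratum topic
  counts default to the reference study's reported counts (newspapers
  5/7, magazines 5/7, nonfiction 5/5, fiction 7/7 for 1800s/1900s).
- Determinism end to end: `run_pipeline()` under a fixed config and seed
  writes byte-identical tables (verified by content hash).

## Validation summary

The test suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) checks, among others:

- exact agreement of windowed counts and MI with an independent
  brute-force scan over random corpora;
- exact agreement of CANS with a direct weighted-mean recomputation, plus
  its convexity bounds;
- recovery of a planted −0.05/decade drift across 200 synthetic corpora:
  mean fitted slope within 10%, t-interval coverage in the nominal band,
  the linear term significant and higher-order terms at their nominal
  false-positive rate — the qualitative linear-only pattern of the
  reference analysis;
- top-10 word recovery of planted disjoint topics and the exact
  closed-form check at K = 1;
- sign and 2-SE recovery of all five planted mixed-model coefficients in
  100 replicates, and the OLS limit at zero decade variance;
- the three reliability checkpoints (identical raters → alpha 1,
  independent raters → alpha ≈ 0, a parallel-test simulation calibrated
  to 0.98).

Problem sizes in these studies (corpus layout above; 200 trend replicates;
200-document topic corpora; 100 mixed-model replicates) were chosen so the
planted effects are comfortably identified at desk scale.

## Known limitations

- Criterion (b) of the inclusion protocol — human judgment of relevance —
  is represented structurally (exclusion list + unrated-word exclusion),
  not behaviorally.
- MI-threshold selection interacts with corpus size: in very small corpora
  the filter is conservative and can clip genuinely associated collocates.
- Only six of the eleven target synonyms of the reference protocol are
  documented; the bundled lexicon ships those six and accepts user
  extensions.
- The mixed model treats synonym-decade rows as exchangeable given the
  decade intercept; serial correlation across decades and synonym-level
  random effects are out of scope, as are autocorrelation-robust trend
  errors.
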