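# agenarr — diachronic analysis of aging narratives

`agenarr` is an R package for measuring how narratives about older adults
evolve across decades of text — a "psychomics" pipeline for diachronic
corpus linguistics applied to ageism as a population-health exposure. It
is written for researchers who have a decade- and genre-tagged corpus
(newspaper, magazine, fiction, nonfiction; years 1810–2019) and want a
reproducible, tested implementation of the full measurement chain:

1. **Concordance & collocation** — find every occurrence of a lexicon of
   "older adult" synonyms (*aged*, *elderly*, *old people*, …), count the
   words within ±4 tokens, and keep, per synonym and decade, the top-100
   collocates by joint frequency with Mutual Information
   `MI = log2( f_joint · N / (f_node · f_coll · W) ) ≥ 3` bits (`W = 8`).
2. **Multi-rater rating** — score retained collocates against rating
   lexicons on sentiment (1 = very negative … 5 = very positive), status,
   warmth, competence, medicalization and ostracism, with Cronbach's
   alpha (Feldt CI) for inter-rater reliability.
3. **CANS** — the Cumulative Aging Narrative Score per decade
   `CANS_d = Σ_s w_{s,d}·mean_{s,d} / Σ_s w_{s,d}`, where each synonym's
   mean collocate sentiment is weighted by the synonym's decade frequency;
   plus the proportion of decades above the neutral threshold (3) and
   linear/quadratic/cubic OLS trends on the decade index.
4. **Topic models** — per genre × century, collapsed-Gibbs LDA over each
   document's retained collocates (Rcpp sampler, seed-deterministic).
5. **Predictor model** — a linear mixed model of the synonym × decade
   sentiment score on the five sociological dimensions, with a random
   intercept per decade (REML via lme4, Wald tests).

Licensed corpora and human raters cannot be redistributed, so the package
ships a **synthetic-data module**: corpora with a planted linear sentiment
drift (expected CANS exactly `b0 + s·d`), planted genre × century topics,
and simulated raters with calibrated reliability — giving analytic ground
truth against which every stage is tested.

## Worked example

Simulate a study-shaped dataset, run the pipeline, inspect the results:

```r
library(agenarr)

spec  <- generator_spec(seed = 42)           # 21 decades x 4 genres, planted drift
paths <- simulate_study_data(spec, "demo")   # corpus.jsonl, rating_lexicon.csv, ...
cfg   <- pipeline_config(corpus = paths[["corpus"]],
                         synonyms = paths[["synonyms"]],
                         lexicons = paths[["lexicon"]], seed = 42)
bundle <- run_pipeline(cfg)

head(as.data.frame(bundle$cans), 4)
#>   decade     cans total_weight n_synonyms
#> 1      0 2.979375           48          6
#> 2      1 3.036458           48          6
#> 3      2 3.210938           48          6
#> 4      3 2.979167           48          6

bundle$trends$linear
#> Polynomial trend, degree 1 (n = 21)
#>        term  estimate      se         p    ci_lo    ci_hi
#> 1 intercept  3.068399 0.05120 4.064e-23  2.96124 3.175560
#> 2        d1 -0.002424 0.00438 5.864e-01 -0.01159 0.006742

bundle$reliability$sentiment
#> Cronbach's alpha = 0.989 (95% CI: 0.987, 0.991), 420 items x 2 raters
```

Reading the output: each row of `cans` is one decade (index 0 = the
1810s); `cans` is the frequency-weighted mean collocate sentiment on the
1–5 scale, with 3 neutral, so decade 2 here reads slightly positive. The
linear trend's `d1` row is the per-decade change in CANS — at this small
default corpus size the planted drift of −0.0068/decade is inside the
confidence interval but not individually significant; recovery studies at
a steeper planted slope (−0.05) identify it in essentially every
replicate (see the acceptance script). Alpha near 0.99 reflects the
simulated raters' calibrated near-perfect agreement.

`write_report(bundle, "results/")` writes the CANS CSV, trend JSON,
reliability JSON, per-stratum topic CSVs, mixed-model tables and a
manifest with content hashes; rerunning the same config reproduces the
hashes exactly. A thin command-line wrapper lives at
`inst/scripts/narratives.R` (`simulate` / `run` subcommands).

## Layout

- `R/` — corpus I/O, collocation, rating, narrative score, topic model,
  predictor model, synthetic data, pipeline.
- `src/` — the collapsed-Gibbs LDA sampler (Rcpp).
- `inst/extdata/synonyms.txt` — the bundled six-term target lexicon.
- `vignettes/aging-narratives-methods.Rmd` — model, assumptions, design
  decisions, generator calibration, limitations.
- `tests/testthat/` — unit, property and study-scale acceptance tests.
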