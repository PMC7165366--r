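# biaobesity

Benchmarking food-industry commitments on population nutrition, the
BIA-Obesity (Business Impact Assessment on obesity and population nutrition)
way. The package is aimed at public-health nutrition researchers running —
or methodologically auditing — a Phase I company assessment: selecting the
companies that dominate a country's packaged-food, quick-service-restaurant
(QSR) and retail markets, scoring their published policies against
band-structured indicators across six domains, consolidating an expert
panel's independent scores, and ranking companies by a sector-weighted
composite.

## What it computes

**Selection.** From a market-share table (company × food subcategory), a
sector's companies are selected when they rank in the top quarter of retail
values of a subcategory, topped up (except for the retailer sector, whose
long tail of small grocers makes the criterion unattainable) until the
selection covers at least 50 percentage points of market share.

**Scoring.** Each indicator has an ordered set of score bands (subsets of
{−10, 0, 2, 2.5, 4, 5, 6, 7.5, 8, 10}); structured evidence attributes are
matched against band predicates, with a deficit band (−10) for companies
that actively oppose public-health measures such as soft-drink taxation.
Per domain *d* and company *c*,

    P_cd = 100 · Σ achieved / Σ max band points   (applicable indicators only)

and the overall weighted score is `S_c = Σ_d (w_d / 100) · P_cd` with the
sector's domain weights `w_d` (summing to 100; renormalised when a domain is
not applicable to a company). Companies are ranked by `S_c`; negative
domain scores pass through.

**Consensus.** The final score of each indicator needs a simple majority of
the panel — at least `floor(n/2) + 1` identical votes (4 of 6) — otherwise a
referee decides. Experts whose overall weighted score for a company falls
outside the Tukey fences (Q1 − 1.5·IQR, Q3 + 1.5·IQR) are flagged for
re-consideration.

**Statistics.** Two-way random-effects absolute-agreement intraclass
correlation, ICC(A,1) and ICC(A,k), with 95% F-based confidence intervals;
the panel agreement rate; exact (full-enumeration) and tie-corrected
Mann-Whitney U; tie-corrected Kruskal-Wallis; and Spearman rank correlation
with exact permutation p-values at small n.

**Synthetic data.** A seeded generator produces market-share frames and
expert score matrices with a latent per-company quality (participation and
global-scope effects), ordinal rater noise and company-level N/A patterns,
so the whole pipeline is testable without the confidential study data.

## Worked example

```r
library(biaobesity)

rubrics <- load_indicators(system.file("extdata", "indicators.yaml", package = "biaobesity"))
weights <- load_weights(system.file("extdata", "weights.yaml", package = "biaobesity"))
table1  <- load_market_share_table(system.file("extdata", "table1_market_share.csv",
                                               package = "biaobesity"))

# company selection in the retailer sector (coverage criterion not applied)
select_companies(table1, "retailer", apply_coverage = FALSE)
#> BIA-Obesity company selection -- sector: retailer
#>   companies selected: 6
#>   relevant market share: 26.2 %

# a full synthetic assessment at the study's scale (33 companies, 6 experts)
cfg    <- sim_config(seed = 2026)
frame  <- generate_market_table(cfg)
roster <- company_roster(frame)
sim    <- generate_panel(cfg, roster, rubrics)
run_assessment(sim$panels, roster, rubrics, weights)
#> BIA-Obesity assessment -- 33 companies
#>   agreement rate: 95.5 %
#>   per-company ICC(A,1) range: [-0.04, 0.94]
#>   overall median score: 13.8 %
#>   participating_vs_not: mann_whitney statistic = 3, p = 1.13e-05
#>   global_vs_other: mann_whitney statistic = 80, p = 0.117
#>   listed_vs_not: mann_whitney statistic = 53, p = 0.393
#>   experts_overall: kruskal_wallis statistic = 0.8, p = 0.977
#>   share_vs_overall: spearman statistic = -0.05, p = 0.79
```

The selection covers the six retailers holding 26.2% of the retail food
market. In the synthetic run, 95.5% of applicable indicator entries reach
the 4-of-6 majority, participating companies score significantly higher
than non-participating ones (Mann-Whitney U = 3, exact p ≈ 1e-5, reflecting
the configured 38-point participation effect), and market share is not
associated with the overall score — the qualitative pattern the generator
is built to emulate. Per-company scorecards and the study-style summary are
written with `build_scorecard()` / `write_scorecard()` and
`render_summary()` / `write_summary()`.

Evidence never enters as free text: a human coder converts published
commitments into the structured attributes declared in the rubric file
(see `inst/extdata/evidence_example.yaml`), and `score_indicator()` maps
them to band scores.

## Package layout

- `R/` — data model and I/O, selection, rubric engine, consensus, scoring,
  statistics, synthetic generator, reporting.
- `inst/extdata/` — example rubric set, sector weights, evidence file, and
  the published company roster with market shares.
- `vignettes/assessment-methods.Rmd` — the model, its assumptions, and the
  package's design decisions.
- `tests/testthat/` — unit, property and end-to-end suites.
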