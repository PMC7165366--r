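---
title: "Methods behind the BIA-Obesity assessment pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the BIA-Obesity assessment pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biaobesity)
```

This vignette documents the models and conventions the package implements,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the procedure left room
for interpretation.

## The assessment model

A Phase I BIA-Obesity assessment benchmarks food companies' *published
commitments* (not their behaviour) across six policy domains: corporate
strategy, product formulation, nutrition labelling, promotion practices,
product accessibility, and relationships with external organisations. The
pipeline has four computational stages.

### 1. Company selection

The sampling frame is a market-share table: one row per (company, food
subcategory) with retail value and percent market share. Two criteria
select companies per sector:

1. within each subcategory, rank companies by descending retail value and
   keep rank `<= ceiling(q * n)` with `q = 0.25` ("the top quarter of
   retail values");
2. add companies in descending total-share order until the selected union
   covers at least `coverage_target * 100 = 50` percentage points of market
   share.

Criterion 2 is skipped for the retailer sector, where a long tail of small
grocers makes 50-point coverage unattainable; when a sector cannot reach
the target the result is *flagged* (`coverage_unmet`), never an error.

Two readings were genuinely open. "Top quarter of retail values" could be a
rank quartile or a value threshold; the rank reading (`rank <=
ceiling(0.25 n)`) is deterministic and is the default, with the fraction
exposed as `quartile_fraction`. And the coverage clause could mean 50
cumulative share points or 50% of the sector's observed total; we implement
cumulative points, which matches how the assessed sectors' coverage figures
(62.9%, 79.1%, 26.2%) are quoted as shares of the whole market. Ties in
retail value break by ascending company id for reproducibility.

### 2. Rubric scoring

Each indicator carries an ordered set of score bands — values in
`[-10, 10]`, typically subsets of {0, 2.5, 5, 7.5, 10} — and each band a
predicate over *structured evidence attributes* (enumerations, booleans,
bounded integers). Evidence never enters as free text: a human coder
translates published commitments into the attribute schema declared at the
top of the rubric file, which keeps the computational boundary testable.
Bands with explicit predicates are evaluated in descending score order;
when none matches, the default floor band (score `<= 0`) applies. Deficit
bands (negative scores, e.g. strong opposition to soft-drink taxation)
carry explicit predicates and are therefore reachable even though the
floor is 0.

The loader *proves* band predicates mutually exclusive by exhaustive
enumeration of the attribute grid, which is what makes band selection
order-independent. Age-band indicators use inclusive cutoffs encoded with
explicit lower and upper bounds (18+ → 10, 16–17 → 8, 14–15 → 6, 12–13 →
4, 1–11 → 2, none → 0), the literal reading of the published bands.

Applicability is a company property: an indicator's applicability predicate
is evaluated over roster fields plus declared portfolio flags (a
beverage-only manufacturer is exempt from a trans-fat target). Structural
N/A is encoded in score files as the literal token `"NA"`; empty cells are
rejected so silent missingness can never masquerade as inapplicability.

The shipped `indicators.yaml` contains one fully worked indicator per
domain plus one applicability example, all marked `status: example`: the
full instrument has many more indicators per domain and is supplied by the
user in the same schema, as are the sector weight allocations.

### 3. Consensus and outlier screening

Experts score independently; the final indicator score requires a simple
majority, `floor(panel_size / 2) + 1` identical votes (4 of 6, 3 of 5, 4 of
7). Unresolved entries go to a referee whose decision *is* the final score
— it does not enter as an additional majority vote, and `majority_reached`
stays false so the agreement rate is unaffected. For simulations the
package provides a deterministic referee (median vote snapped to the
nearest band, lower band on ties); real assessments substitute the human
decision. The agreement rate is the percent of applicable entries reaching
majority.

Before consensus, each expert's own scores are pushed through the full
weighting to an overall score per company; experts outside the Tukey fences
`[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged for re-consideration. Quartiles
use linear interpolation (R `quantile` type 7) — no quantile convention was
prescribed, so one is fixed package-wide and documented. The fences are
computed per company rather than pooled across companies; per-company is
the reading consistent with returning outliers "to the relevant experts"
during each company's scoring round.

### 4. Weighted scoring and ranking

Domain percent-of-points excludes non-applicable indicators from numerator
and denominator alike; a domain with no applicable indicator is N/A and the
remaining weights are renormalised to 100 before the overall sum. The
alternative — zero-filling — would conflate inapplicability with failure.
Negative overall scores are allowed (deficit bands pass through); scores
are capped at 100 by construction. Ranks use the minimum-rank ("1224")
convention; medians use the midpoint convention for even counts. All
percents are computed at full precision and rounded to one decimal only at
display time.

## The statistical battery

- **ICC.** Inter-rater reliability per company uses the two-way
  random-effects, absolute-agreement ICC on the (indicator × rater) matrix
  of band scores, rows with any N/A dropped listwise and scores unweighted.
  Both `ICC(A,1)` and `ICC(A,k)` are reported, with 95% confidence bounds
  from the F-distribution construction (Satterthwaite degrees of freedom for
  the single measure; Spearman-Brown transform of those bounds for the
  average measure). A matrix with zero total variance is perfect agreement
  by convention (estimate 1, degenerate interval).
- **Mann-Whitney.** Midranks for ties; statistic `U = min(U_a, U_b)`. The
  two-sided p-value is exact by full enumeration of group assignments when
  `min(n_a, n_b) <= 8` and no tie spans the groups, using the doubled
  smaller-tail convention `min(1, 2 min(P(U <= u), P(U >= u)))`; otherwise
  the tie-corrected normal approximation without continuity correction. A
  seeded 100,000-resample permutation method is available when an exact
  answer is wanted beyond the enumeration limit.
- **Kruskal-Wallis.** Tie-corrected H against chi-square with `g - 1`
  degrees of freedom; with all observations identical the statistic is 0
  and p is 1. At `g = 2` the statistic is the square of the Mann-Whitney
  z, so the two p-values coincide — a property the tests assert to 1e-6.
- **Spearman.** `rho` is the Pearson correlation of midranks; exact p by
  enumeration of all `n!` permutations for `n <= 9`, else the t
  approximation on `n - 2` degrees of freedom. Zero rank variance yields a
  flagged, undefined result rather than a number.

The enumeration limits (8 for U, 9 for rho) keep the exact paths below a
second while covering panel-sized samples; the study-scale two-group
comparisons (e.g. 6 vs 27 companies) take the tie-corrected approximation.

## The synthetic-data generator

The generator's defaults are the study conditions: 22 manufacturers, 5 QSR,
6 retailers holding about 63, 79 and 26 share points; 6/33 companies
participating and listed, 21/33 global; a 6-member panel. Within a sector,
company `i` receives share proportional to `i^-concentration` — a
concentrated head with a long tail, flattest for retailers. Each company
has a latent quality on the percent scale,

    theta_c = base_sector + 38 · participating + 7 · global + N(0, 8),

where 38 and 7 mirror the published participating vs non-participating
(45.1 vs 6.9) and global vs other (13.0 vs 5.8) median contrasts. Within a
company, indicators vary around `theta_c` by `N(0, indicator_sd = 20)` —
commitments differ across domains, and this between-indicator variance is
what gives panels their high inter-rater ICC. The per-indicator quality
maps to the *true* band by nearest percent level of the indicator's
non-negative band lattice (lower band on midpoint ties); each expert
reports the true band with probability `p_agree = 0.85`, else slips to an
adjacent band. For a 6-member panel, `p_agree = 0.85` implies roughly a 95%
simple-majority agreement rate, matching the study's 94.2%. N/A masks are
drawn once per company (rate 0.05) and copied across experts. Deficit bands
are never generated: opposition is an evidence-coding fact, not rater
noise.

A single root seed drives independent substreams per company and per
expert, so enlarging a roster never perturbs existing companies' draws —
the property the regression tests rely on.

What the generator does *not* emulate: real evidence collection (companies'
actual document trails), correlated rater idiosyncrasies (an expert who is
systematically harsh across companies), domain-specific effect patterns,
or deficit-band behaviour. Passing recovery tests therefore shows the
pipeline's arithmetic and inferential machinery is sound under the assumed
model, not that the instrument itself is valid or reliable in the field.

For ICC recovery studies a second generator, `generate_icc_matrix()`, draws
from the plain two-way random-effects model with known variance components,
where `ICC(A,1) = sigma_r^2 / (sigma_r^2 + sigma_c^2 + sigma_e^2)` in
closed form; the band-slip model has edge clamping that admits no such
closed form.

## Numerical conventions and degenerate inputs

- Band scores are half-unit decimals compared with absolute tolerance 1e-9,
  never exact float equality.
- Weight files must sum to exactly 100 per sector and are never silently
  renormalised at load; renormalisation happens only per company for N/A
  domains.
- `consolidate()` demands exactly `panel_size` votes (a missing rater is an
  error, not an imputation); `flag_outlier_experts()` refuses panels below
  3, where fences are undefined.
- Empty sectors, empty selections, all-identical score matrices, zero rank
  variance and all-N/A domains each have a defined, tested behaviour
  (error, flag or convention) documented on the corresponding function.

## Problem sizes used in the shipped test suites

The property suites run at sizes chosen to make brute-force oracles exact
and fast: exhaustive vote-vector enumeration up to panels of 7 on 3 bands;
full `C(n, n_a)` Mann-Whitney enumeration up to n = 14; all `7!` Spearman
permutations; ICC bias over 1,000 replicates of 100 × 6 matrices; and
effect recovery over 1,000 seeded pipelines of 30 companies. The recovered
participation effect is asserted within ±10 points of the configured 40:
the score scale is a band lattice with steps up to 25 points on the
coarsest indicators, so the weighted composite carries quantization error
of about half the weighted mean step even with a perfect panel.

## Known limitations

- The shipped rubric set is illustrative (one indicator per domain); study
  instruments are user-supplied, so package results are not comparable to
  published company scores, which also depend on the full indicator list
  and the study's confidential evidence.
- The ICC is computed on unweighted band scores per company; whether
  weighting preceded the published reliability figures is not stated, and
  the unweighted choice is fixed here.
- Exact Mann-Whitney p-values are unavailable when ties span groups; the
  tie-corrected approximation (or the seeded permutation method) is used
  instead.
- Scorecard layout is original to this package; only its numeric semantics
  (weights, percents, the 0.05 display-rounding consistency bound) are
  constrained.
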