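Package: biaobesity
Title: Business Impact Assessment of Food-Industry Nutrition Commitments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the BIA-Obesity (Business Impact Assessment on
    population nutrition and obesity) Phase I company assessment as a
    reusable pipeline: market-share based company selection, rubric scoring
    of policy commitments across six domains, expert-panel consensus under
    the simple-majority rule with referee tie-break and Tukey-fence outlier
    screening, sector-weighted composite scoring and ranking, and the
    accompanying statistical battery (two-way random absolute-agreement
    intraclass correlation with confidence intervals, exact and
    tie-corrected Mann-Whitney, Kruskal-Wallis, and Spearman rank tests).
    A seeded synthetic-data generator emulates market-share frames and
    expert score matrices so every stage is testable without confidential
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
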