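test_that("the six published worked examples score 10, 2.5, 7.5, 2, -10, 10", {
  rub <- fixture_rubrics()
  sch <- rub$attributes
  expect_equal(score_indicator(
    list(commitment_level = "national", publicly_available = TRUE),
    rub$indicators$cs_overarching_commitment, sch), 10)
  expect_equal(score_indicator(
    list(commitment_level = "national", publicly_available = TRUE,
         specificity = "vague"),
    rub$indicators$pf_reformulation_commitment, sch), 2.5)
  expect_equal(score_indicator(
    list(fop_format = "interpretive_some"),
    rub$indicators$nl_fop_labelling, sch), 7.5)
  expect_equal(score_indicator(
    list(age_cutoff_years = 6),
    rub$indicators$pp_marketing_age_policy, sch), 2)
  expect_equal(score_indicator(
    list(fiscal_position = "strongly_opposed"),
    rub$indicators$pa_fiscal_policy_position, sch), -10)
  expect_equal(score_indicator(
    list(donations_disclosure = "national_public"),
    rub$indicators$er_political_donations, sch), 10)
})

test_that("age bands follow the inclusive cutoff reading", {
  rub <- fixture_rubrics()$indicators$pp_marketing_age_policy
  cases <- list(c(18, 10), c(21, 10), c(17, 8), c(16, 8), c(15, 6), c(14, 6),
                c(13, 4), c(12, 4), c(11, 2), c(9, 2), c(1, 2), c(0, 0))
  for (cs in cases) {
    expect_equal(score_indicator(list(age_cutoff_years = cs[1]), rub), cs[2],
                 info = paste("cutoff", cs[1]))
  }
})

test_that("absent or unknown evidence lands on the floor band", {
  rub <- fixture_rubrics()
  for (ind in rub$indicators) {
    expect_equal(score_indicator(list(), ind), ind$default_score)
  }
  expect_equal(score_indicator(list(fiscal_position = "unknown"),
                               rub$indicators$pa_fiscal_policy_position), 0)
})

test_that("scores always lie in the indicator's band set", {
  rub <- fixture_rubrics()
  set.seed(404)
  schema <- rub$attributes
  random_evidence <- function() {
    picked <- sample(names(schema), sample.int(length(schema), 1))
    ev <- lapply(picked, function(a) {
      s <- schema[[a]]
      switch(s$type,
             enum = sample(unlist(s$values), 1),
             boolean = sample(c(TRUE, FALSE), 1),
             integer = sample(seq(s$min, s$max), 1))
    })
    names(ev) <- picked
    ev
  }
  for (i in 1:80) {
    ind <- rub$indicators[[sample.int(length(rub$indicators), 1)]]
    s <- score_indicator(random_evidence(), ind, schema)
    expect_true(any(abs(ind$band_scores - s) < 1e-9))
  }
})

test_that("band evaluation is order-independent for the shipped rubrics", {
  rub <- fixture_rubrics()
  set.seed(77)
  schema <- rub$attributes
  shuffled_score <- function(evidence, rubric) {
    explicit <- Filter(function(b) !b$default, rubric$bands)
    explicit <- explicit[sample.int(length(explicit))]
    for (b in explicit) {
      if (biaobesity:::band_matches(b, evidence)) return(b$score)
    }
    rubric$default_score
  }
  evs <- list(
    list(commitment_level = "global", publicly_available = TRUE),
    list(commitment_level = "national", publicly_available = FALSE,
         specificity = "specific"),
    list(fop_format = "numeric_some"),
    list(age_cutoff_years = 16),
    list(fiscal_position = "weak_support")
  )
  inds <- list(rub$indicators$cs_overarching_commitment,
               rub$indicators$pf_reformulation_commitment,
               rub$indicators$nl_fop_labelling,
               rub$indicators$pp_marketing_age_policy,
               rub$indicators$pa_fiscal_policy_position)
  for (i in seq_along(evs)) {
    ref <- score_indicator(evs[[i]], inds[[i]], schema)
    for (rep in 1:5) expect_equal(shuffled_score(evs[[i]], inds[[i]]), ref)
  }
})

test_that("non-exclusive bands and undeclared attributes are configuration errors", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c(
    'version: "1"', "attributes:", "  x:", "    type: enum",
    "    values: [a, b]", "indicators:",
    "  - id: bad", "    domain: corporate_strategy", "    question: q",
    "    bands:",
    "      - {score: 10, when: {x: [a, b]}}",
    "      - {score: 5, when: {x: a}}",
    "      - {score: 0, default: true}"), tmp)
  expect_error(load_indicators(tmp), "mutually exclusive",
               class = "bia_config_error")

  writeLines(c(
    'version: "1"', "attributes:", "  x:", "    type: enum",
    "    values: [a, b]", "indicators:",
    "  - id: bad2", "    domain: corporate_strategy", "    question: q",
    "    bands:",
    "      - {score: 10, when: {mystery: a}}",
    "      - {score: 0, default: true}"), tmp)
  expect_error(load_indicators(tmp), "undeclared",
               class = "bia_config_error")

  # evidence using an attribute the schema does not declare is rejected
  rub <- fixture_rubrics()
  expect_error(
    score_indicator(list(flavour = "salty"),
                    rub$indicators$cs_overarching_commitment, rub$attributes),
    "undeclared", class = "bia_validation_error")
})

test_that("applicability excludes the trans-fat indicator for beverage-only companies", {
  rub <- fixture_rubrics()
  bev <- toy_company(sector = "manufacturer")
  ids <- applicable_indicators(bev, list(sells_food = FALSE,
                                         sells_beverages_only = TRUE), rub)
  expect_false("pf_transfat_target" %in% ids)
  expect_true("pf_reformulation_commitment" %in% ids)

  all_flags <- applicable_indicators(bev, list(sells_food = TRUE,
                                               sells_beverages_only = TRUE), rub)
  expect_setequal(all_flags, names(rub$indicators))

  # a missing flag fails the predicate: indicator treated as not applicable
  none <- applicable_indicators(bev, list(), rub)
  expect_false("pf_transfat_target" %in% none)
})

test_that("applicability agrees with direct predicate evaluation on random flags", {
  rub <- fixture_rubrics()
  comp <- toy_company()
  set.seed(31)
  for (i in 1:20) {
    flags <- list(sells_food = sample(c(TRUE, FALSE), 1),
                  sells_beverages_only = sample(c(TRUE, FALSE), 1))
    ids <- applicable_indicators(comp, flags, rub)
    # only the trans-fat indicator is conditional in the shipped set
    expected <- names(rub$indicators)
    if (!isTRUE(flags$sells_food)) {
      expected <- setdiff(expected, "pf_transfat_target")
    }
    expect_setequal(ids, expected)
  }
})
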