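# Shared fixtures: everything is built in code or loaded from the packaged
# plain-text examples.

extdata <- function(name) {
  path <- system.file("extdata", name, package = "biaobesity")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  path
}

fixture_rubrics <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_indicators(extdata("indicators.yaml"))
    cache
  }
})

fixture_weights <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_weights(extdata("weights.yaml"))
    cache
  }
})

fixture_table1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_market_share_table(extdata("table1_market_share.csv"))
    }
    cache
  }
})

# A tiny three-band rubric set built in code, convenient for consensus and
# scoring tests: two domains, three indicators.
toy_rubrics <- function() {
  tmp <- withr_local_tempfile()
  writeLines(c(
    'version: "1.0"',
    "attributes:",
    "  level:",
    "    type: enum",
    "    values: [high, mid, low]",
    "flags:",
    "  sells_food:",
    "    type: boolean",
    "indicators:",
    "  - id: ind_a",
    "    domain: corporate_strategy",
    "    question: a",
    "    bands:",
    "      - {score: 10, when: {level: high}}",
    "      - {score: 5, when: {level: mid}}",
    "      - {score: 0, default: true}",
    "  - id: ind_b",
    "    domain: corporate_strategy",
    "    question: b",
    "    bands:",
    "      - {score: 10, when: {level: high}}",
    "      - {score: 2.5, when: {level: mid}}",
    "      - {score: 0, default: true}",
    "  - id: ind_c",
    "    domain: product_formulation",
    "    question: c",
    "    bands:",
    "      - {score: 10, when: {level: high}}",
    "      - {score: -10, when: {level: low}}",
    "      - {score: 0, default: true}"
  ), tmp)
  load_indicators(tmp)
}

withr_local_tempfile <- function() {
  tmp <- tempfile(fileext = ".yaml")
  tmp
}

# equal weights over the two toy domains require all six; spread the rest
toy_weights <- function() {
  w <- c(corporate_strategy = 50, product_formulation = 50,
         nutrition_labelling = 0, promotion_practices = 0,
         product_accessibility = 0, external_relationships = 0)
  domain_weights(manufacturer = w, qsr = w, retailer = w)
}

toy_panel <- function(company_id = "c1", scores, experts = NULL) {
  if (is.null(experts)) experts <- sprintf("e%d", seq_len(ncol(scores)))
  dimnames(scores) <- list(c("ind_a", "ind_b", "ind_c")[seq_len(nrow(scores))],
                           experts)
  panel_scores(company_id, scores)
}

toy_company <- function(company_id = "c1", sector = "manufacturer",
                        scope = "national", participating = FALSE,
                        listed = FALSE) {
  data.frame(company_id = company_id, name = company_id, sector = sector,
             scope = scope, participating = participating, listed = listed,
             total_share = 10, stringsAsFactors = FALSE)
}
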