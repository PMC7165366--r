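#' Build a per-company scorecard document
#'
#' Assembles the numbers a company scorecard presents: the header
#' (name, sector, scope, participation), a domain table with the company's
#' percent-of-points, the sector weight and the weighted contribution per
#' domain, the overall weighted score and rank. Free-text slots
#' (`key_strengths`, `recommendations`) are empty by default. All numeric
#' fields are rounded to one decimal at render time only; the build asserts
#' that the overall score recomputed from the *printed* (rounded) domain
#' table agrees with the printed overall within 0.05.
#'
#' @param company one-row roster entry.
#' @param scorecard one-row entry of a ranked scorecard table (from
#'   [rank_and_summarise()]), with `P_` domain columns, `overall`, `rank`.
#' @param weights a `"bia_weights"` object.
#' @return list of class `"bia_scorecard_doc"`.
#' @export
build_scorecard <- function(company, scorecard, weights) {
  company <- as.list(company)
  scorecard <- as.list(scorecard)
  w <- weights[[company$sector]]
  if (is.null(w)) {
    stop_bia("no weights for sector '", company$sector, "'",
             class = "bia_validation_error")
  }
  if (!identical(company$company_id, scorecard$company_id)) {
    stop_bia("company / scorecard mismatch: ", company$company_id, " vs ",
             scorecard$company_id, class = "bia_validation_error")
  }
  doms <- names(w)
  p <- vapply(doms, function(d) scorecard[[paste0("P_", d)]] %||% NA_real_,
              numeric(1))
  ok <- !is.na(p)
  w_eff <- rep(NA_real_, length(doms))
  w_eff[ok] <- w[ok] / sum(w[ok]) * 100
  tab <- data.frame(domain = doms, weight = w_eff, percent = p,
                    contribution = w_eff / 100 * p, stringsAsFactors = FALSE)
  doc <- structure(list(
    company_id = company$company_id,
    header = list(name = company$name, sector = company$sector,
                  scope = company$scope,
                  participating = isTRUE(company$participating)),
    domain_table = tab,
    overall = scorecard$overall,
    rank = scorecard$rank,
    key_strengths = "",
    recommendations = ""
  ), class = "bia_scorecard_doc")
  printed_overall <- round1(doc$overall)
  recomputed <- sum(w_eff[ok] / 100 * round1(p[ok]))
  if (abs(printed_overall - recomputed) > 0.05 + 1e-9) {
    stop_bia("scorecard display rounding inconsistency for ",
             company$company_id, class = "bia_validation_error")
  }
  doc
}

#' Render a scorecard as markdown lines
#'
#' @param doc a `"bia_scorecard_doc"`.
#' @return character vector of markdown lines.
#' @export
render_scorecard_markdown <- function(doc) {
  stopifnot(inherits(doc, "bia_scorecard_doc"))
  tab <- doc$domain_table
  lines <- c(
    paste0("# Scorecard: ", doc$header$name),
    "",
    paste0("- Sector: ", doc$header$sector),
    paste0("- Scope: ", doc$header$scope),
    paste0("- Participating: ", ifelse(doc$header$participating, "yes", "no")),
    "",
    "| Domain | Weight | Percent of points | Contribution |",
    "|---|---|---|---|",
    vapply(seq_len(nrow(tab)), function(i) {
      if (is.na(tab$percent[i])) {
        sprintf("| %s | - | N/A | - |", tab$domain[i])
      } else {
        sprintf("| %s | %.1f | %.1f | %.1f |", tab$domain[i], tab$weight[i],
                tab$percent[i], tab$contribution[i])
      }
    }, character(1)),
    "",
    sprintf("**Overall weighted score: %.1f%%** (rank %d)", doc$overall,
            as.integer(doc$rank)),
    "",
    "## Key strengths", doc$key_strengths,
    "",
    "## Recommendations", doc$recommendations
  )
  lines
}

#' Write a scorecard as markdown plus its JSON twin
#'
#' @param doc a `"bia_scorecard_doc"`.
#' @param dir output directory (created if absent).
#' @return named character vector of the two paths, invisibly.
#' @export
write_scorecard <- function(doc, dir) {
  stopifnot(inherits(doc, "bia_scorecard_doc"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  md <- file.path(dir, paste0("scorecard_", doc$company_id, ".md"))
  js <- file.path(dir, paste0("scorecard_", doc$company_id, ".json"))
  writeLines(render_scorecard_markdown(doc), md)
  jsonlite::write_json(unclass(doc), js, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(markdown = md, json = js))
}

#' Read back a scorecard JSON twin
#'
#' @param path JSON path written by [write_scorecard()].
#' @return a `"bia_scorecard_doc"`.
#' @export
read_scorecard <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$domain_table <- as.data.frame(x$domain_table)
  x$rank <- as.numeric(x$rank)
  structure(x, class = "bia_scorecard_doc")
}

#' Render the study-style summary
#'
#' Builds the machine-readable summary (overall median, medians by sector
#' and domain, the ranked company table, and the statistical test results)
#' and its markdown rendering. Every number printed in the markdown is
#' formatted from the JSON twin — a consistency check re-derives each
#' printed value from the twin on every render.
#'
#' @param ranking a `"bia_ranking"` from [rank_and_summarise()].
#' @param stat_report optional `"bia_stat_report"`; when `NULL` the tests
#'   section is rendered as absent.
#' @return list of class `"bia_summary_doc"`: `json` (the twin, a plain
#'   list) and `markdown` (character lines).
#' @export
render_summary <- function(ranking, stat_report = NULL) {
  stopifnot(inherits(ranking, "bia_ranking"))
  sc <- ranking$scorecards
  twin <- list(
    n_companies = nrow(sc),
    median_overall = ranking$median_overall,
    median_by_sector = as.list(ranking$median_by_sector),
    median_by_domain = as.list(ranking$median_by_domain),
    companies = sc,
    agreement_rate = if (!is.null(stat_report)) stat_report$agreement_rate,
    tests = if (!is.null(stat_report) && !is.null(stat_report$tests))
      stat_report$tests
  )
  md <- c(
    "# Assessment summary",
    "",
    sprintf("Companies assessed: %d", twin$n_companies),
    sprintf("Overall median weighted score: %.1f%%", twin$median_overall),
    "",
    "## Medians by sector",
    vapply(names(twin$median_by_sector), function(s)
      sprintf("- %s: %.1f%%", s, twin$median_by_sector[[s]]), character(1)),
    "",
    "## Medians by domain",
    vapply(names(twin$median_by_domain), function(d)
      sprintf("- %s: %.1f%%", sub("^P_", "", d), twin$median_by_domain[[d]]),
      character(1)),
    ""
  )
  if (is.null(twin$tests)) {
    md <- c(md, "## Group comparisons", "", "_No statistical report supplied._")
  } else {
    md <- c(md, "## Group comparisons", "",
            "| Comparison | Test | Statistic | p | Method |", "|---|---|---|---|---|",
            vapply(seq_len(nrow(twin$tests)), function(i) {
              t <- twin$tests[i, ]
              sprintf("| %s | %s | %.3f | %.4f | %s |", t$comparison, t$test,
                      t$statistic, t$p_value, t$method)
            }, character(1)))
  }
  doc <- structure(list(json = twin, markdown = md), class = "bia_summary_doc")
  check_summary_consistency(doc)
  doc
}

# every number printed in the markdown must be re-derivable from the twin
check_summary_consistency <- function(doc) {
  twin <- doc$json
  md <- paste(doc$markdown, collapse = "\n")
  expect_in <- function(fmt, val) {
    if (!grepl(sprintf(fmt, val), md, fixed = TRUE)) {
      stop_bia("summary markdown out of sync with its JSON twin (missing ",
               sprintf(fmt, val), ")", class = "bia_validation_error")
    }
  }
  expect_in("%.1f%%", twin$median_overall)
  for (s in names(twin$median_by_sector)) expect_in("%.1f%%", twin$median_by_sector[[s]])
  for (d in names(twin$median_by_domain)) expect_in("%.1f%%", twin$median_by_domain[[d]])
  invisible(TRUE)
}

#' Write the summary markdown and JSON twin
#'
#' @param doc a `"bia_summary_doc"`.
#' @param dir output directory.
#' @return named character vector of paths, invisibly.
#' @export
write_summary <- function(doc, dir) {
  stopifnot(inherits(doc, "bia_summary_doc"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  md <- file.path(dir, "summary.md")
  js <- file.path(dir, "summary.json")
  writeLines(doc$markdown, md)
  jsonlite::write_json(doc$json, js, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(c(markdown = md, json = js))
}
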