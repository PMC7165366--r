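#' Domain percent-of-points for one company
#'
#' For each of the six domains, the company's percent of the total available
#' points over the indicators *applicable to it*:
#' `P = 100 * sum(achieved) / sum(max band score)`, with non-applicable
#' indicators excluded from both numerator and denominator. Deficit bands
#' (negative scores) pass through, so a domain percent may be negative — a
#' single-indicator domain scored -10 against a 10-point maximum yields
#' -100. A domain with no applicable indicator is `NA` for the company and
#' is later excluded from weighting with renormalisation.
#'
#' @param final_scores named numeric vector of consolidated indicator scores
#'   (`NA` marks structural non-applicability); names are indicator ids.
#' @param rubrics a `"bia_rubric_set"`.
#' @return named numeric vector over all six [bia_domains] (`NA` for a
#'   domain with no applicable indicator, including domains the rubric set
#'   does not cover).
#' @export
domain_scores <- function(final_scores, rubrics) {
  stopifnot(inherits(rubrics, "bia_rubric_set"))
  doms <- bia_domains
  out <- vapply(doms, function(d) {
    ids <- names(rubrics$indicators)[
      vapply(rubrics$indicators, `[[`, character(1), "domain") == d]
    ids <- intersect(ids, names(final_scores))
    app <- ids[!is.na(final_scores[ids])]
    if (length(app) == 0L) return(NA_real_)
    maxpts <- sum(vapply(rubrics$indicators[app], `[[`, numeric(1), "max_score"))
    if (maxpts <= 0) {
      stop_bia("domain '", d, "' has zero maximum points over applicable ",
               "indicators", class = "bia_validation_error")
    }
    100 * sum(final_scores[app]) / maxpts
  }, numeric(1))
  names(out) <- doms
  out
}

#' Sector-weighted overall score
#'
#' `S = sum_d (w_d / 100) * P_d` over the six domains, using the sector's
#' weight allocation (which sums to 100). When a domain is `NA` for the
#' company (no applicable indicator) the remaining weights are renormalised
#' to 100 before summation, so inapplicability is never conflated with a
#' zero score. A domain absent from `domain_percents` altogether (rather
#' than marked `NA`) is an error.
#'
#' @param domain_percents named numeric vector of domain percents (may
#'   contain `NA` marks).
#' @param weights a `"bia_weights"` object.
#' @param sector the company's sector.
#' @return overall weighted percent (full precision; may be negative, never
#'   above 100).
#' @export
overall_weighted_score <- function(domain_percents, weights, sector) {
  stopifnot(inherits(weights, "bia_weights"))
  w <- weights[[sector]]
  if (is.null(w)) {
    stop_bia("no weights for sector '", sector, "'",
             class = "bia_validation_error")
  }
  missing <- setdiff(names(w), names(domain_percents))
  if (length(missing) > 0L) {
    stop_bia("domain percent missing (without N/A mark) for: ",
             paste(missing, collapse = ", "), class = "bia_validation_error")
  }
  p <- domain_percents[names(w)]
  ok <- !is.na(p)
  if (!any(ok)) {
    stop_bia("all domains are N/A for this company; overall score undefined",
             class = "bia_validation_error")
  }
  w_eff <- w[ok] / sum(w[ok]) * 100
  sum(w_eff / 100 * p[ok])
}

#' Build scorecards from consensus results
#'
#' Pipeline glue: per-company consolidated indicator scores become domain
#' percents and a sector-weighted overall score.
#'
#' @param consensus data.frame of [consolidate_panel()] rows for one or more
#'   companies (all entries must be resolved: an applicable indicator with
#'   no final score is an error).
#' @param roster roster data.frame (see [company_roster()]).
#' @param rubrics a `"bia_rubric_set"`.
#' @param weights a `"bia_weights"` object.
#' @return data.frame with one row per company: roster fields, one `P_`
#'   column per domain, `overall`.
#' @export
score_companies <- function(consensus, roster, rubrics, weights) {
  unresolved <- consensus$applicable %in% TRUE & is.na(consensus$final_score)
  if (any(unresolved)) {
    stop_bia("unresolved consensus entries (needs_referee without referee) for: ",
             paste(unique(consensus$company_id[unresolved]), collapse = ", "),
             class = "bia_validation_error")
  }
  doms <- bia_domains
  rows <- lapply(unique(consensus$company_id), function(cid) {
    sub <- consensus[consensus$company_id == cid, , drop = FALSE]
    fs <- sub$final_score
    names(fs) <- sub$indicator_id
    who <- roster[roster$company_id == cid, , drop = FALSE]
    if (nrow(who) != 1L) {
      stop_bia("company '", cid, "' not found (or duplicated) in roster",
               class = "bia_validation_error")
    }
    dp <- domain_scores(fs, rubrics)
    overall <- overall_weighted_score(dp, weights, who$sector)
    out <- data.frame(company_id = cid, name = who$name, sector = who$sector,
                      scope = who$scope, participating = who$participating,
                      listed = who$listed, stringsAsFactors = FALSE)
    for (d in doms) out[[paste0("P_", d)]] <- dp[[d]]
    out$overall <- overall
    out
  })
  do.call(rbind, rows)
}

#' Rank companies and summarise medians
#'
#' Ranks descending by overall weighted score with minimum-rank ("1224")
#' ties, and computes the medians the study reports: the overall median
#' across all companies, medians by sector, and medians by domain. Medians
#' use the midpoint convention for even counts.
#'
#' @param scorecards data.frame from [score_companies()] (needs
#'   `company_id`, `sector`, `overall` and `P_` domain columns).
#' @return list of class `"bia_ranking"`: `scorecards` (with `rank` added,
#'   sorted by rank), `median_overall`, `median_by_sector`,
#'   `median_by_domain`.
#' @export
rank_and_summarise <- function(scorecards) {
  stopifnot(is.data.frame(scorecards), nrow(scorecards) >= 1L)
  sc <- scorecards
  sc$rank <- rank(-sc$overall, ties.method = "min")
  sc <- sc[order(sc$rank, sc$company_id), , drop = FALSE]
  rownames(sc) <- NULL
  dom_cols <- grep("^P_", names(sc), value = TRUE)
  structure(list(
    scorecards = sc,
    median_overall = stats::median(sc$overall),
    median_by_sector = vapply(split(sc$overall, sc$sector), stats::median,
                              numeric(1)),
    median_by_domain = vapply(sc[dom_cols],
                              function(x) stats::median(x, na.rm = TRUE),
                              numeric(1))
  ), class = "bia_ranking")
}

#' @export
print.bia_ranking <- function(x, ...) {
  cat("BIA-Obesity ranking --", nrow(x$scorecards), "companies\n")
  cat("  overall median:", round1(x$median_overall), "%\n")
  cat("  medians by sector:",
      paste(names(x$median_by_sector), round1(x$median_by_sector),
            sep = "=", collapse = ", "), "\n")
  top <- utils::head(x$scorecards, 5L)
  cat("  top companies:",
      paste(top$company_id, round1(top$overall), sep = ":", collapse = ", "),
      "\n")
  invisible(x)
}
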