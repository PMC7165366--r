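#' Select companies from a market-share frame
#'
#' Applies the two study selection criteria within one sector:
#'
#' 1. **Top quarter per subcategory** — within each food subcategory,
#'    companies are ranked by descending retail value and those with rank
#'    `<= ceiling(quartile_fraction * n)` are selected.
#' 2. **Market-share coverage** (skipped when `apply_coverage = FALSE`, as
#'    the study did for the retailer sector with its long tail of small
#'    grocers) — companies are added in descending total-share order until
#'    the cumulative share of the selected union reaches
#'    `coverage_target * 100` percentage points.
#'
#' Ties in retail value (and in total share) are broken by ascending
#' `company_id`, making selection deterministic. If even the full sector
#' cannot reach the coverage target the result is flagged `coverage_unmet`
#' rather than erroring.
#'
#' @param table a `bia_market_share` table.
#' @param sector one of [bia_sectors].
#' @param quartile_fraction fraction of each subcategory's ranking retained
#'   by criterion 1 (default 0.25, in `(0, 1]`).
#' @param coverage_target cumulative-share target for criterion 2 as a
#'   fraction (default 0.5 for "at least 50% of the relevant market share").
#' @param apply_coverage whether criterion 2 applies.
#' @return object of class `"bia_selection"`: `sector`, `company_ids`
#'   (descending total share), `relevant_market_share` (full precision),
#'   `coverage_unmet`, `trace` (per-subcategory ranking with selection
#'   tags), and `criteria` (per-company tag table).
#' @export
select_companies <- function(table, sector,
                             quartile_fraction = 0.25,
                             coverage_target = 0.5,
                             apply_coverage = TRUE) {
  stopifnot(inherits(table, "bia_market_share"))
  if (!sector %in% bia_sectors) {
    stop_bia("unknown sector '", sector, "'", class = "bia_validation_error")
  }
  stopifnot(quartile_fraction > 0, quartile_fraction <= 1,
            coverage_target > 0, coverage_target <= 1)
  rows <- table[table$sector == sector, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_bia("no rows for sector '", sector, "' in the market-share table",
             class = "bia_validation_error")
  }

  total_share <- tapply(rows$share_pct, rows$company_id, sum)
  companies <- names(sort(total_share, decreasing = TRUE))
  # deterministic order: descending share, then ascending id
  companies <- companies[order(-total_share[companies], companies)]

  # criterion 1: rank within subcategory by descending retail value
  trace <- do.call(rbind, lapply(split(rows, rows$subcategory), function(sub) {
    ord <- order(-sub$retail_value, sub$company_id)
    sub <- sub[ord, , drop = FALSE]
    k <- ceiling(quartile_fraction * nrow(sub))
    data.frame(subcategory = sub$subcategory,
               company_id = sub$company_id,
               retail_value = sub$retail_value,
               rank = seq_len(nrow(sub)),
               selected_top_quartile = seq_len(nrow(sub)) <= k,
               stringsAsFactors = FALSE)
  }))
  rownames(trace) <- NULL
  by_c1 <- unique(trace$company_id[trace$selected_top_quartile])

  selected <- by_c1
  by_c2 <- character(0)
  coverage_unmet <- FALSE
  if (apply_coverage) {
    target <- coverage_target * 100
    cum <- sum(total_share[selected])
    for (cid in companies) {
      if (cum >= target - 1e-9) break
      if (cid %in% selected) next
      selected <- c(selected, cid)
      by_c2 <- c(by_c2, cid)
      cum <- cum + total_share[[cid]]
    }
    coverage_unmet <- cum < target - 1e-9
  }

  selected <- companies[companies %in% selected]
  criteria <- data.frame(
    company_id = selected,
    total_share = as.numeric(total_share[selected]),
    by_top_quartile = selected %in% by_c1,
    by_coverage = selected %in% by_c2,
    stringsAsFactors = FALSE
  )
  structure(list(
    sector = sector,
    company_ids = selected,
    relevant_market_share = sum(total_share[selected]),
    coverage_unmet = coverage_unmet,
    trace = trace,
    criteria = criteria,
    quartile_fraction = quartile_fraction,
    coverage_target = if (apply_coverage) coverage_target else NA_real_
  ), class = "bia_selection")
}

#' Relevant market share of a selection
#'
#' The cumulative percent market share covered by the selected companies,
#' reported to one decimal as in the study's reporting style (e.g. a
#' retailer selection covering shares 9.3, 7.0, 3.4, 2.9, 2.6 and 1.0
#' reports 26.2).
#'
#' @param selection a `"bia_selection"` object.
#' @return percent, rounded to 1 decimal.
#' @export
relevant_market_share <- function(selection) {
  stopifnot(inherits(selection, "bia_selection"))
  round1(selection$relevant_market_share)
}

#' @export
print.bia_selection <- function(x, ...) {
  cat("BIA-Obesity company selection -- sector:", x$sector, "\n")
  cat("  companies selected:", length(x$company_ids), "\n")
  cat("  relevant market share:", round1(x$relevant_market_share), "%\n")
  if (isTRUE(x$coverage_unmet)) {
    cat("  note: coverage target", x$coverage_target * 100,
        "% not reachable in this sector\n")
  }
  invisible(x)
}
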