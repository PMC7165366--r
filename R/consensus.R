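#' Consolidate one indicator's expert votes by simple majority
#'
#' The final score for an indicator is the score cast by a simple majority
#' of the panel: at least `floor(panel_size / 2) + 1` identical votes (4 of
#' a 6-member panel, 3 of 5, 4 of 7). When no score reaches the threshold
#' the entry needs a referee — the referee's decision is recorded via
#' [resolve_with_referee()] and decides the outcome directly rather than
#' entering as an additional majority vote.
#'
#' @param votes numeric vector of band scores, one per expert.
#' @param panel_size expected number of voters; fewer (or more) votes than
#'   `panel_size` is an error (a missing or duplicated rater).
#' @param bands optional numeric vector of the indicator's allowed band
#'   values; votes are snapped to bands with tolerance `1e-9`.
#' @return list of class `"bia_consensus_entry"`: `final_score` (or `NA`),
#'   `majority_reached`, `needs_referee`, `referee_score` (`NA` until
#'   resolved), `histogram` (named vote counts), `threshold`.
#' @export
consolidate <- function(votes, panel_size, bands = NULL) {
  if (length(votes) == 0L) {
    stop_bia("no votes supplied", class = "bia_validation_error")
  }
  if (anyNA(votes)) {
    stop_bia("votes contain NA; consolidate only applicable indicators",
             class = "bia_validation_error")
  }
  if (length(votes) != panel_size) {
    stop_bia("got ", length(votes), " vote(s) for a panel of ", panel_size,
             " (missing or duplicated rater)", class = "bia_validation_error")
  }
  if (!is.null(bands)) {
    idx <- match_band(votes, bands)
    if (anyNA(idx)) {
      stop_bia("vote(s) outside the indicator's band set: ",
               paste(unique(votes[is.na(idx)]), collapse = ", "),
               class = "bia_validation_error")
    }
    votes <- bands[idx]
    levels <- bands
  } else {
    levels <- sort(unique(votes))
  }
  counts <- vapply(levels, function(v) sum(abs(votes - v) <= 1e-9), integer(1))
  names(counts) <- format(levels, trim = TRUE)
  threshold <- floor(panel_size / 2) + 1L
  top <- which(counts >= threshold)
  majority <- length(top) == 1L  # >= threshold is necessarily unique
  structure(list(
    final_score = if (majority) levels[top] else NA_real_,
    majority_reached = majority,
    needs_referee = !majority,
    referee_score = NA_real_,
    histogram = counts[counts > 0L],
    threshold = threshold,
    panel_size = panel_size
  ), class = "bia_consensus_entry")
}

#' Record a referee decision for an unresolved entry
#'
#' When the simple-majority rule fails, an additional academic referee makes
#' the final decision. The referee's score becomes the final score directly;
#' `majority_reached` stays `FALSE` so agreement statistics are unaffected.
#'
#' @param entry a `"bia_consensus_entry"` with `needs_referee = TRUE`.
#' @param referee_score the referee's band score.
#' @param bands optional band set to validate against.
#' @return the updated entry.
#' @export
resolve_with_referee <- function(entry, referee_score, bands = NULL) {
  stopifnot(inherits(entry, "bia_consensus_entry"))
  if (!entry$needs_referee) {
    stop_bia("entry already has a majority decision",
             class = "bia_validation_error")
  }
  if (!is.null(bands) && is.na(match_band(referee_score, bands))) {
    stop_bia("referee score ", referee_score, " is not an allowed band",
             class = "bia_validation_error")
  }
  entry$final_score <- referee_score
  entry$referee_score <- referee_score
  entry$needs_referee <- FALSE
  entry
}

#' Deterministic median-band referee
#'
#' A referee policy usable in simulations and pipelines: the median of the
#' cast votes, snapped to the nearest allowed band (ties between two bands
#' go to the lower band). Real assessments substitute a human decision.
#'
#' @param votes numeric vector of cast votes.
#' @param bands allowed band values for the indicator.
#' @return a single band score.
#' @export
referee_median_band <- function(votes, bands) {
  m <- stats::median(votes)
  bands <- sort(bands)
  d <- abs(bands - m)
  bands[which(d <= min(d) + 1e-12)][1L]
}

#' Consolidate a full company panel
#'
#' Runs [consolidate()] over every indicator of a company's score matrix.
#' Structurally non-applicable indicators (all-`NA` rows) are carried with
#' `applicable = FALSE` and no final score. Unresolved entries are settled
#' by the `referee` function when one is supplied.
#'
#' @param panel a [panel_scores()] object.
#' @param rubrics a `"bia_rubric_set"` (supplies each indicator's band set).
#' @param referee `NULL`, or a `function(votes, bands)` returning the
#'   referee's band score (see [referee_median_band()]).
#' @return data.frame with one row per indicator: `company_id`,
#'   `indicator_id`, `applicable`, `majority_reached`, `needs_referee`,
#'   `referee_used`, `final_score`.
#' @export
consolidate_panel <- function(panel, rubrics, referee = NULL) {
  stopifnot(inherits(panel, "bia_panel_scores"),
            inherits(rubrics, "bia_rubric_set"))
  inds <- rownames(panel$scores)
  rows <- lapply(inds, function(ind) {
    votes <- panel$scores[ind, ]
    if (all(is.na(votes))) {
      return(data.frame(company_id = panel$company_id, indicator_id = ind,
                        applicable = FALSE, majority_reached = NA,
                        needs_referee = FALSE, referee_used = FALSE,
                        final_score = NA_real_, stringsAsFactors = FALSE))
    }
    bands <- rubrics$indicators[[ind]]$band_scores
    entry <- consolidate(votes, panel$panel_size, bands = bands)
    if (entry$needs_referee && !is.null(referee)) {
      entry <- resolve_with_referee(entry, referee(votes, bands), bands = bands)
    }
    data.frame(company_id = panel$company_id, indicator_id = ind,
               applicable = TRUE, majority_reached = entry$majority_reached,
               needs_referee = entry$needs_referee,
               referee_used = !is.na(entry$referee_score),
               final_score = entry$final_score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Panel agreement rate
#'
#' Percent of applicable (non-N/A) consolidated indicator entries on which
#' the panel reached the simple-majority rule; e.g. 1787 majority-reached
#' entries out of 1897 applicable give 94.2 (to one decimal).
#'
#' @param results data.frame from [consolidate_panel()] (rows from several
#'   companies may be concatenated), or any data.frame with logical columns
#'   `applicable` and `majority_reached`.
#' @return percent at full precision; round for display.
#' @export
agreement_rate <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("applicable", "majority_reached") %in% names(results)))
  ok <- results[results$applicable %in% TRUE, , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop_bia("no applicable indicator entries; agreement rate undefined",
             class = "bia_validation_error")
  }
  100 * mean(ok$majority_reached)
}

#' Flag outlier experts by Tukey fences on their overall weighted scores
#'
#' Before consensus, each expert's own scores are pushed through the full
#' weighting (domain percent-of-points, then sector weights) to give that
#' expert's overall weighted score for the company. Experts whose overall
#' score falls strictly outside the Tukey fences `[Q1 - 1.5 IQR,
#' Q3 + 1.5 IQR]` are flagged for re-consideration. Quartiles use linear
#' interpolation (R quantile type 7), the convention fixed across this
#' package.
#'
#' @param panel a [panel_scores()] object.
#' @param company one-row roster entry (needs `sector`).
#' @param weights a `"bia_weights"` object.
#' @param rubrics a `"bia_rubric_set"`.
#' @return list of class `"bia_outlier_report"`: `company_id`,
#'   `expert_scores` (named), `q1`, `q3`, `fence_low`, `fence_high`,
#'   `flagged` (expert ids).
#' @export
flag_outlier_experts <- function(panel, company, weights, rubrics) {
  stopifnot(inherits(panel, "bia_panel_scores"))
  if (panel$panel_size < 3L) {
    stop_bia("Tukey fences are undefined for panels smaller than 3",
             class = "bia_validation_error")
  }
  sector <- as.list(company)$sector
  overall <- vapply(colnames(panel$scores), function(e) {
    sc <- panel$scores[, e]
    names(sc) <- rownames(panel$scores)
    dp <- domain_scores(sc, rubrics)
    overall_weighted_score(dp, weights, sector)
  }, numeric(1))
  q <- stats::quantile(overall, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  flagged <- names(overall)[overall < lo - 1e-12 | overall > hi + 1e-12]
  structure(list(company_id = panel$company_id, expert_scores = overall,
                 q1 = q[1], q3 = q[2], fence_low = lo, fence_high = hi,
                 flagged = flagged),
            class = "bia_outlier_report")
}
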