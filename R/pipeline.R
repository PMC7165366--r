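#' Run the full Phase I assessment pipeline
#'
#' From per-company expert score matrices to the study-style outputs:
#' consensus consolidation under the simple-majority rule (with a referee
#' policy for unresolved entries), the panel agreement rate, per-company
#' inter-rater ICC, sector-weighted scorecards with ranking and medians, and
#' the group-comparison battery (Mann-Whitney for participating vs
#' non-participating, global vs regional/national scope, listed vs
#' non-listed; Kruskal-Wallis across experts' per-company overall scores;
#' Spearman for market share vs overall score).
#'
#' Group tests are skipped (with a note) when a grouping has an empty side;
#' this keeps the pipeline usable on small or degenerate rosters.
#'
#' @param panels named list of [panel_scores()] objects.
#' @param roster roster data.frame including a `total_share` column (see
#'   [company_roster()]).
#' @param rubrics a `"bia_rubric_set"`.
#' @param weights a `"bia_weights"` object.
#' @param referee referee policy function (default [referee_median_band()]).
#' @return list of class `"bia_assessment"`: `consensus` (all consolidated
#'   rows), `agreement_rate`, `icc` (named list of per-company
#'   `"bia_icc"`), `ranking` (a `"bia_ranking"`), `tests` (named list of
#'   `"bia_test_result"`), `stat_report`.
#' @export
run_assessment <- function(panels, roster, rubrics, weights,
                           referee = referee_median_band) {
  consensus <- do.call(rbind, lapply(panels, consolidate_panel,
                                     rubrics = rubrics, referee = referee))
  rownames(consensus) <- NULL
  agree <- agreement_rate(consensus)

  icc <- lapply(panels, function(p) {
    m <- p$scores[!apply(is.na(p$scores), 1L, all), , drop = FALSE]
    if (nrow(m) >= 2L && stats::sd(as.vector(m)) >= 0) {
      icc_two_way_random_absolute(m)
    } else NULL
  })
  icc <- Filter(Negate(is.null), icc)

  scorecards <- score_companies(consensus, roster, rubrics, weights)
  ranking <- rank_and_summarise(scorecards)
  sc <- ranking$scorecards

  tests <- list()
  two_group <- function(flag, label) {
    a <- sc$overall[flag]; b <- sc$overall[!flag]
    if (length(a) >= 1L && length(b) >= 1L) {
      tests[[label]] <<- mann_whitney(a, b)
    }
  }
  two_group(sc$participating, "participating_vs_not")
  two_group(sc$scope == "global", "global_vs_other")
  two_group(sc$listed, "listed_vs_not")

  # per-expert overall weighted scores across companies, compared across
  # the panel members
  expert_scores <- list()
  for (p in panels) {
    who <- roster[roster$company_id == p$company_id, , drop = FALSE]
    for (e in colnames(p$scores)) {
      s <- p$scores[, e]
      names(s) <- rownames(p$scores)
      val <- overall_weighted_score(domain_scores(s, rubrics), weights,
                                    who$sector)
      expert_scores[[e]] <- c(expert_scores[[e]], val)
    }
  }
  if (length(expert_scores) >= 2L) {
    tests$experts_overall <- kruskal_wallis(expert_scores)
  }

  share <- roster$total_share[match(sc$company_id, roster$company_id)]
  if (length(sc$overall) >= 3L && !anyNA(share)) {
    tests$share_vs_overall <- spearman_rank(share, sc$overall)
  }

  structure(list(
    consensus = consensus,
    agreement_rate = agree,
    icc = icc,
    ranking = ranking,
    tests = tests,
    stat_report = compile_stat_report(icc, agree, tests)
  ), class = "bia_assessment")
}

#' Assemble a statistical report object
#'
#' Collects ICC range, agreement rate and test results, validating the
#' report invariants (ICC within `[-1, 1]` with ordered CI, agreement rate
#' within `[0, 100]`, p-values within `[0, 1]`).
#'
#' @param icc named list of `"bia_icc"` objects (may be empty).
#' @param agreement agreement rate percent.
#' @param tests named list of `"bia_test_result"` objects.
#' @return list of class `"bia_stat_report"`.
#' @export
compile_stat_report <- function(icc, agreement, tests) {
  stopifnot(agreement >= 0, agreement <= 100)
  icc_tab <- NULL
  if (length(icc) > 0L) {
    icc_tab <- do.call(rbind, lapply(names(icc), function(cid) {
      v <- icc[[cid]]
      stopifnot(v$single$estimate >= -1, v$single$estimate <= 1,
                v$single$ci_low <= v$single$estimate + 1e-9,
                v$single$estimate <= v$single$ci_high + 1e-9)
      data.frame(company_id = cid,
                 icc_single = v$single$estimate,
                 icc_single_low = v$single$ci_low,
                 icc_single_high = v$single$ci_high,
                 icc_average = v$average$estimate,
                 icc_average_low = v$average$ci_low,
                 icc_average_high = v$average$ci_high,
                 stringsAsFactors = FALSE)
    }))
  }
  test_tab <- NULL
  if (length(tests) > 0L) {
    test_tab <- do.call(rbind, lapply(names(tests), function(nm) {
      t <- tests[[nm]]
      stopifnot(is.na(t$p_value) || (t$p_value >= 0 && t$p_value <= 1))
      data.frame(comparison = nm, test = t$name,
                 statistic = t$statistic, p_value = t$p_value,
                 method = t$method, stringsAsFactors = FALSE)
    }))
  }
  structure(list(icc = icc_tab, agreement_rate = agreement, tests = test_tab),
            class = "bia_stat_report")
}

#' @export
print.bia_assessment <- function(x, ...) {
  cat("BIA-Obesity assessment --", nrow(x$ranking$scorecards), "companies\n")
  cat("  agreement rate:", round1(x$agreement_rate), "%\n")
  if (length(x$icc) > 0L) {
    est <- vapply(x$icc, function(v) v$single$estimate, numeric(1))
    cat("  per-company ICC(A,1) range: [", round(min(est), 2), ", ",
        round(max(est), 2), "]\n", sep = "")
  }
  cat("  overall median score:", round1(x$ranking$median_overall), "%\n")
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat("  ", nm, ": ", t$name, " statistic = ", round(t$statistic, 2),
        ", p = ", format.pval(t$p_value, digits = 3), "\n", sep = "")
  }
  invisible(x)
}
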