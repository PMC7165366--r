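#' Simulation configuration for synthetic assessment data
#'
#' Defines the generative model used throughout the test suite: a
#' market-share frame with a concentrated head and a long tail of small
#' companies per sector, and an expert-panel model in which each company has
#' a latent policy quality on the percent scale,
#' `theta = base + delta_participating * participating +
#' delta_global * global + Normal(0, latent_sd)`, clamped to `[0, 100]`.
#' Each indicator maps `theta` to a *true* band by nearest percent level of
#' its band lattice; each expert reports the true band with probability
#' `p_agree` and otherwise slips to an adjacent band (up or down with equal
#' probability, reflecting at the ends). Indicator applicability masks are
#' drawn once per company and copied across experts.
#'
#' Defaults mirror the published study conditions: 22 manufacturers, 5 QSR
#' and 6 retailers with sector market-share totals near 63%, 79% and 26%;
#' 6 of 33 companies participating and listed, 21 of 33 global; a
#' participation effect of 38 percent (the study's participating vs
#' non-participating medians were 45.1% vs 6.9%) and a global-scope effect
#' of 7 (13.0% vs 5.8%); `p_agree = 0.85`, which for a 6-member panel gives
#' a simple-majority agreement probability of about 95%, matching the
#' study's 94.2% agreement rate; and a 6-member panel.
#'
#' @param n_companies named integer vector per sector.
#' @param prop_participating,prop_global,prop_listed company-type
#'   probabilities.
#' @param base_percent named numeric: latent base quality per sector.
#' @param delta_participating,delta_global non-negative effects on the
#'   percent scale.
#' @param latent_sd standard deviation of company-level noise.
#' @param indicator_sd standard deviation of per-indicator variation around
#'   the company's latent quality (commitments differ across domains within
#'   a company; this is what gives a panel matrix its between-row variance
#'   and hence a high inter-rater ICC when `p_agree` is high).
#' @param p_agree probability an expert reports the true band.
#' @param na_rate probability an indicator is structurally N/A for a
#'   company.
#' @param panel_size number of experts (>= 5).
#' @param concentration power-law exponent of the within-sector share
#'   allocation (larger = more concentrated head); named per sector or a
#'   single number.
#' @param sector_total_share named numeric: total percent share the
#'   generated companies hold per sector.
#' @param n_subcategories subcategories per sector in the market frame.
#' @param seed root seed (mandatory); all draws run in substreams keyed by
#'   sector, company and expert, so adding a company never perturbs existing
#'   companies' draws.
#' @return validated list of class `"bia_sim_config"`.
#' @export
sim_config <- function(n_companies = c(manufacturer = 22L, qsr = 5L, retailer = 6L),
                       prop_participating = 6 / 33,
                       prop_global = 21 / 33,
                       prop_listed = 6 / 33,
                       base_percent = c(manufacturer = 10, qsr = 5, retailer = 5),
                       delta_participating = 38,
                       delta_global = 7,
                       latent_sd = 8,
                       indicator_sd = 20,
                       p_agree = 0.85,
                       na_rate = 0.05,
                       panel_size = 6L,
                       concentration = c(manufacturer = 1.1, qsr = 0.8,
                                         retailer = 0.7),
                       sector_total_share = c(manufacturer = 63, qsr = 79,
                                              retailer = 26),
                       n_subcategories = 3L,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop_bia("sim_config requires an explicit seed", class = "bia_config_error")
  }
  sectors <- names(n_companies)
  stopifnot(all(sectors %in% bia_sectors), all(n_companies >= 1L))
  for (p in c(prop_participating, prop_global, prop_listed, p_agree, na_rate)) {
    if (p < 0 || p > 1) {
      stop_bia("probabilities must lie in [0, 1]", class = "bia_config_error")
    }
  }
  if (p_agree <= 0) {
    stop_bia("p_agree must be positive", class = "bia_config_error")
  }
  stopifnot(delta_participating >= 0, delta_global >= 0, latent_sd >= 0,
            indicator_sd >= 0, panel_size >= 5L,
            is.finite(delta_participating), is.finite(delta_global))
  if (length(concentration) == 1L) {
    concentration <- stats::setNames(rep(concentration, length(sectors)), sectors)
  }
  structure(list(
    n_companies = n_companies,
    prop_participating = prop_participating,
    prop_global = prop_global,
    prop_listed = prop_listed,
    base_percent = base_percent,
    delta_participating = delta_participating,
    delta_global = delta_global,
    latent_sd = latent_sd,
    indicator_sd = indicator_sd,
    p_agree = p_agree,
    na_rate = na_rate,
    panel_size = as.integer(panel_size),
    concentration = concentration,
    sector_total_share = sector_total_share,
    n_subcategories = as.integer(n_subcategories),
    seed = as.integer(seed)
  ), class = "bia_sim_config")
}

#' Generate a synthetic market-share table
#'
#' Within each sector, company `i` of `n` receives a share proportional to
#' `i^-concentration` scaled so the sector's shares sum to its configured
#' total (kept at or below 100). Retail values are shares expressed in an
#' arbitrary currency unit (40 per share point). Companies are assigned to
#' subcategories round-robin. Company attributes (scope, participation,
#' listing) are drawn in per-company substreams.
#'
#' @param config a [sim_config()] object.
#' @return a validated `bia_market_share` table.
#' @export
generate_market_table <- function(config) {
  stopifnot(inherits(config, "bia_sim_config"))
  rows <- list()
  for (sector in names(config$n_companies)) {
    n <- config$n_companies[[sector]]
    alpha <- config$concentration[[sector]]
    total <- config$sector_total_share[[sector]]
    raw <- seq_len(n)^(-alpha)
    shares <- raw / sum(raw) * total
    for (i in seq_len(n)) {
      cid <- sprintf("%s_%02d", sector, i)
      sub_seed <- substream_seed(config$seed, "company", cid)
      draws <- with_seed(sub_seed, stats::runif(3))
      scope <- if (draws[1] < config$prop_global) "global" else
        sample_regional_national(draws[1], config$prop_global)
      rows[[cid]] <- data.frame(
        company_id = cid,
        name = sprintf("Synthetic %s %02d", sector, i),
        sector = sector,
        scope = scope,
        participating = draws[2] < config$prop_participating,
        listed = draws[3] < config$prop_listed,
        subcategory = sprintf("%s_cat_%d", sector,
                              (i - 1L) %% config$n_subcategories + 1L),
        retail_value = shares[i] * 40,
        share_pct = shares[i],
        stringsAsFactors = FALSE
      )
    }
  }
  market_share_table(do.call(rbind, rows))
}

# split the non-global mass evenly between regional and national using the
# same uniform draw, so scope is a deterministic function of one draw
sample_regional_national <- function(u, p_global) {
  if (u < p_global + (1 - p_global) / 2) "regional" else "national"
}

#' Generate synthetic expert-panel scores with ground truth
#'
#' Implements the latent-quality rater model described in [sim_config()] for
#' a company roster against a rubric set. Each company's latent percent
#' `theta` is perturbed per indicator by `Normal(0, indicator_sd)` (clamped
#' to `[0, 100]`); the nearest-level lattice then maps that per-indicator
#' quality to a true band: each non-negative band corresponds to the percent
#' level `100 * band / max_band` and the band whose level is closest is true
#' (lower band on midpoint ties). Deficit bands are never generated —
#' opposition evidence is an evidence-coding fact, not rater noise.
#'
#' @param config a [sim_config()] object.
#' @param roster roster data.frame (see [company_roster()]); defaults to the
#'   roster of a table generated from `config`.
#' @param rubrics a `"bia_rubric_set"`.
#' @return list of class `"bia_sim_panel"`: `panels` (named list of
#'   [panel_scores()] objects) and `truth` (`theta` and `true_bands` per
#'   company, plus the config).
#' @export
generate_panel <- function(config, roster, rubrics) {
  stopifnot(inherits(config, "bia_sim_config"),
            inherits(rubrics, "bia_rubric_set"), nrow(roster) >= 1L,
            length(rubrics$indicators) >= 1L)
  inds <- names(rubrics$indicators)
  panels <- list()
  theta_all <- numeric(0)
  true_bands <- list()
  theta_ind_all <- list()
  for (ci in seq_len(nrow(roster))) {
    who <- roster[ci, , drop = FALSE]
    cid <- who$company_id
    c_seed <- substream_seed(config$seed, "panel", cid)
    draws <- with_seed(c_seed, {
      list(noise = stats::rnorm(1, 0, config$latent_sd),
           eta = stats::rnorm(length(inds), 0, config$indicator_sd),
           na_mask = stats::runif(length(inds)) < config$na_rate)
    })
    theta <- config$base_percent[[who$sector]] +
      config$delta_participating * as.numeric(who$participating) +
      config$delta_global * as.numeric(who$scope == "global") +
      draws$noise
    theta <- clamp(theta, 0, 100)
    theta_ind <- clamp(theta + draws$eta, 0, 100)
    names(theta_ind) <- inds
    na_mask <- draws$na_mask
    if (all(na_mask)) na_mask[1L] <- FALSE  # keep every company assessable

    tb <- vapply(seq_along(inds), function(j) {
      true_band_for(theta_ind[j], rubrics$indicators[[inds[j]]])
    }, numeric(1))
    names(tb) <- inds

    m <- matrix(NA_real_, nrow = length(inds), ncol = config$panel_size,
                dimnames = list(inds, sprintf("expert_%d", seq_len(config$panel_size))))
    for (e in seq_len(config$panel_size)) {
      e_seed <- substream_seed(config$seed, "expert", cid, e)
      u <- with_seed(e_seed, stats::runif(2 * length(inds)))
      for (j in seq_along(inds)) {
        if (na_mask[j]) next
        lattice <- nonneg_bands(rubrics$indicators[[inds[j]]])
        pos <- match_band(tb[j], lattice)
        if (u[2 * j - 1] >= config$p_agree) {
          step <- if (u[2 * j] < 0.5) -1L else 1L
          pos2 <- pos + step
          if (pos2 < 1L || pos2 > length(lattice)) pos2 <- pos - step
          pos <- pos2
        }
        m[j, e] <- lattice[pos]
      }
    }
    panels[[cid]] <- panel_scores(cid, m, rubrics = rubrics,
                                  min_panel = min(5L, config$panel_size))
    theta_all[cid] <- theta
    true_bands[[cid]] <- tb
    theta_ind_all[[cid]] <- theta_ind
  }
  structure(list(panels = panels,
                 truth = list(theta = theta_all,
                              theta_indicator = theta_ind_all,
                              true_bands = true_bands,
                              config = config)),
            class = "bia_sim_panel")
}

nonneg_bands <- function(rubric) {
  sort(rubric$band_scores[rubric$band_scores >= 0])
}

# nearest percent level of the indicator's non-negative band lattice;
# midpoint ties go to the lower band
true_band_for <- function(theta, rubric) {
  lattice <- nonneg_bands(rubric)
  levels <- 100 * lattice / max(lattice)
  d <- abs(levels - theta)
  lattice[which(d <= min(d) + 1e-12)][1L]
}

#' Generate a score matrix with known variance components
#'
#' Draws `y[i, j] = row_i + col_j + e[i, j]` with independent normal
#' components — the two-way random-effects model under which the
#' absolute-agreement ICC has the closed form
#' `sigma_r^2 / (sigma_r^2 + sigma_c^2 + sigma_e^2)` (single measure).
#' Used for reliability recovery studies of [icc_two_way_random_absolute()].
#'
#' @param n rows (rated items), `k` columns (raters).
#' @param k number of raters.
#' @param sigma_row,sigma_col,sigma_err component standard deviations.
#' @param seed seed.
#' @return list: `matrix`, `icc_single_true`, `icc_average_true`.
#' @export
generate_icc_matrix <- function(n, k, sigma_row, sigma_col, sigma_err, seed) {
  m <- with_seed(seed, {
    rows <- stats::rnorm(n, 0, sigma_row)
    cols <- stats::rnorm(k, 0, sigma_col)
    outer(rows, rep(1, k)) + outer(rep(1, n), cols) +
      matrix(stats::rnorm(n * k, 0, sigma_err), n, k)
  })
  tot <- sigma_row^2 + sigma_col^2 + sigma_err^2
  list(matrix = m,
       icc_single_true = sigma_row^2 / tot,
       icc_average_true = sigma_row^2 /
         (sigma_row^2 + (sigma_col^2 + sigma_err^2) / k))
}
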