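test_that("the packaged roster fixture loads with the published share totals", {
  tab <- fixture_table1()
  expect_s3_class(tab, "bia_market_share")
  expect_equal(nrow(tab), 33L)
  sums <- tapply(tab$share_pct, tab$sector, sum)
  expect_equal(unname(sums["retailer"]), 26.2)
  # manufacturer/QSR totals reflect print rounding of per-company shares
  expect_lt(abs(sums[["manufacturer"]] - 62.9), 0.2 + 1e-9)
  expect_lt(abs(sums[["qsr"]] - 79.1), 0.2 + 1e-9)
  expect_equal(sum(tab$listed), 6L)
})

test_that("market-share validation rejects malformed input", {
  tab <- as.data.frame(fixture_table1())
  expect_error(market_share_table(tab[-1, -match("share_pct", names(tab))]),
               "share_pct", class = "bia_schema_error")
  bad <- tab
  bad$retail_value[3] <- -1
  expect_error(market_share_table(bad), "retail_value",
               class = "bia_validation_error")
  dup <- rbind(tab, tab[1, ])
  expect_error(market_share_table(dup), "duplicated",
               class = "bia_validation_error")
  bad_sector <- tab
  bad_sector$sector[1] <- "bakery"
  expect_error(market_share_table(bad_sector), "sector",
               class = "bia_validation_error")
  over <- tab
  over$share_pct[over$sector == "qsr"] <- 25
  expect_error(market_share_table(over), "exceed",
               class = "bia_validation_error")
})

test_that("an empty file with only a header yields an empty table", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(paste("company_id,name,sector,scope,participating,listed,",
                   "subcategory,retail_value,share_pct", sep = ""), tmp)
  tab <- load_market_share_table(tmp)
  expect_equal(nrow(tab), 0L)
  expect_equal(nrow(company_roster(tab)), 0L)
})

test_that("market-share tables round-trip through CSV field-for-field", {
  tab <- fixture_table1()
  tmp <- tempfile(fileext = ".csv")
  write_market_share_table(tab, tmp)
  back <- load_market_share_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("panel scores load, validate bands and round-trip losslessly", {
  rub <- toy_rubrics()
  tmp <- tempfile(fileext = ".csv")
  rows <- expand.grid(indicator_id = c("ind_a", "ind_b", "ind_c"),
                      expert_id = sprintf("e%d", 1:6),
                      stringsAsFactors = FALSE)
  rows$company_id <- "c1"
  rows$score <- rep(c("10", "2.5", "NA"), times = 6)
  utils::write.csv(rows[c("company_id", "indicator_id", "expert_id", "score")],
                   tmp, row.names = FALSE)
  panels <- load_panel_scores(tmp, rub)
  expect_named(panels, "c1")
  expect_equal(panels$c1$panel_size, 6L)
  expect_true(all(is.na(panels$c1$scores["ind_c", ])))
  expect_equal(unname(panels$c1$scores["ind_b", ]), rep(2.5, 6))

  tmp2 <- tempfile(fileext = ".csv")
  write_panel_scores(panels, tmp2)
  back <- load_panel_scores(tmp2, rub)
  expect_equal(back$c1$scores, panels$c1$scores)
  expect_equal(back$c1$panel_size, panels$c1$panel_size)
})

test_that("invalid panel scores are rejected at load, never propagated", {
  rub <- toy_rubrics()
  base <- expand.grid(indicator_id = c("ind_a", "ind_b", "ind_c"),
                      expert_id = sprintf("e%d", 1:6),
                      stringsAsFactors = FALSE)
  base$company_id <- "c1"

  # a score outside the band set names the allowed bands in the error
  bad <- base
  bad$score <- "10"
  bad$score[bad$indicator_id == "ind_b" & bad$expert_id == "e1"] <- "3"
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(bad[c("company_id", "indicator_id", "expert_id", "score")],
                   tmp, row.names = FALSE)
  expect_error(load_panel_scores(tmp, rub), "0, 2.5, 10",
               class = "bia_validation_error")

  # N/A must be constant across experts for a (company, indicator)
  bad2 <- base
  bad2$score <- "10"
  bad2$score[bad2$indicator_id == "ind_c" & bad2$expert_id == "e1"] <- "NA"
  utils::write.csv(bad2[c("company_id", "indicator_id", "expert_id", "score")],
                   tmp, row.names = FALSE)
  expect_error(load_panel_scores(tmp, rub), "inconsistent",
               class = "bia_validation_error")

  # empty cells are silent missingness, not structural N/A
  bad3 <- base
  bad3$score <- "10"
  bad3$score[1] <- ""
  utils::write.csv(bad3[c("company_id", "indicator_id", "expert_id", "score")],
                   tmp, row.names = FALSE, quote = TRUE)
  expect_error(load_panel_scores(tmp, rub), "empty",
               class = "bia_validation_error")

  # fewer than five experts is not a panel
  small <- base[base$expert_id %in% c("e1", "e2", "e3", "e4"), ]
  small$score <- "10"
  utils::write.csv(small[c("company_id", "indicator_id", "expert_id", "score")],
                   tmp, row.names = FALSE)
  expect_error(load_panel_scores(tmp, rub), "at least 5",
               class = "bia_validation_error")
})

test_that("weights must sum to exactly 100 per sector and are never renormalised", {
  w <- fixture_weights()
  for (s in names(w)) expect_equal(sum(w[[s]]), 100)
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c('version: "1"', "weights:", "  qsr:",
               "    corporate_strategy: 50", "    product_formulation: 49",
               "    nutrition_labelling: 0", "    promotion_practices: 0",
               "    product_accessibility: 0", "    external_relationships: 0"),
             tmp)
  expect_error(load_weights(tmp), "sum to 99", class = "bia_validation_error")
})

test_that("synthetic generator output survives the write-read round trip", {
  rub <- fixture_rubrics()
  cfg <- sim_config(n_companies = c(manufacturer = 4L, retailer = 3L),
                    seed = 11)
  tab <- generate_market_table(cfg)
  sim <- generate_panel(cfg, company_roster(tab), rub)

  t1 <- tempfile(fileext = ".csv")
  write_market_share_table(tab, t1)
  expect_equal(as.data.frame(load_market_share_table(t1)), as.data.frame(tab))

  t2 <- tempfile(fileext = ".csv")
  write_panel_scores(sim$panels, t2)
  back <- load_panel_scores(t2, rub)
  for (cid in names(sim$panels)) {
    expect_equal(back[[cid]]$scores, sim$panels[[cid]]$scores)
  }
})
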