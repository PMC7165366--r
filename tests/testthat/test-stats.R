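# Statistical battery: every estimator is checked against an independent
# route (base-R ANOVA / tests, closed forms, or brute-force enumeration
# written separately from the implementation).

test_that("absolute-agreement ICC matches the ANOVA mean-squares oracle on a 5x4 matrix", {
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9), nrow = 5, byrow = TRUE)
  r <- icc_two_way_random_absolute(m)

  # independent mean squares via base-R two-way ANOVA
  d <- data.frame(y = as.vector(m),
                  row = factor(rep(1:5, 4)), col = factor(rep(1:4, each = 5)))
  tab <- summary(stats::aov(y ~ row + col, data = d))[[1]]
  msr <- tab["row", "Mean Sq"]; msc <- tab["col", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- 5; k <- 4
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  expect_equal(r$single$estimate, icc1, tolerance = 1e-10)
  expect_equal(r$average$estimate, icck, tolerance = 1e-10)
  expect_equal(unname(r$ms), c(msr, msc, mse), tolerance = 1e-10)

  # frozen reference values (cross-checked against an independent
  # implementation of McGraw & Wong's ICC(A,1)/ICC(A,k) with 95% CI)
  expect_equal(r$single$estimate, 0.3258813413585554, tolerance = 1e-12)
  expect_equal(r$average$estimate, 0.6591304347826087, tolerance = 1e-12)
  expect_equal(round(c(r$single$ci_low, r$single$ci_high), 2), c(0.02, 0.83))
  expect_equal(round(c(r$average$ci_low, r$average$ci_high), 2), c(0.09, 0.95))
})

test_that("ICC degenerate and perfect-agreement cases follow their conventions", {
  # identical columns, unequal rows: perfect absolute agreement
  m <- matrix(rep(c(1, 5, 9, 3), 4), ncol = 4)
  r <- icc_two_way_random_absolute(m)
  expect_equal(r$single$estimate, 1)
  # all cells equal: defined as 1 with degenerate CI
  r2 <- icc_two_way_random_absolute(matrix(7, 4, 3))
  expect_equal(r2$single$estimate, 1)
  expect_equal(c(r2$single$ci_low, r2$single$ci_high), c(1, 1))
  expect_error(icc_two_way_random_absolute(matrix(1:4, 1, 4)),
               "at least 2", class = "bia_validation_error")
  # invariant: average measure >= single measure when both non-negative
  set.seed(12)
  for (i in 1:10) {
    mm <- matrix(rnorm(30), 6, 5) + rnorm(6)
    rr <- icc_two_way_random_absolute(mm)
    if (rr$single$estimate >= 0) {
      expect_gte(rr$average$estimate, rr$single$estimate - 1e-12)
    }
    expect_lte(rr$single$ci_low, rr$single$estimate + 1e-9)
    expect_gte(rr$single$ci_high, rr$single$estimate - 1e-9)
  }
})

test_that("ICC under a pure-noise null is centred at zero", {
  set.seed(2024)
  reps <- 200
  est <- replicate(reps, {
    m <- matrix(rnorm(60 * 6), 60, 6)
    icc_two_way_random_absolute(m)$single$estimate
  })
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(reps) + 0.01)
})

test_that("Mann-Whitney handles separation, symmetry and the exact path", {
  sep <- mann_whitney(c(10, 20, 30), c(1, 2, 3))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$method, "exact")

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 16 / 2)
  expect_equal(same$p_value, 1)

  # exact p equals enumeration over all C(8,4) assignments (independent
  # loop over combinations, doubled smaller-tail convention)
  a <- c(1.2, 3.4, 0.5, 2.2); b <- c(4.1, 5.0, 2.8, 3.9)
  res <- mann_whitney(a, b)
  expect_equal(res$method, "exact")
  pooled <- c(a, b); r <- rank(pooled)
  ua_obs <- sum(r[1:4]) - 10
  combos <- combn(8, 4)
  ua_all <- apply(combos, 2, function(idx) sum(r[idx]) - 10)
  p_oracle <- min(1, 2 * min(mean(ua_all <= ua_obs), mean(ua_all >= ua_obs)))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  # cross-group ties push the auto path to the tie-corrected approximation,
  # which agrees with base R without continuity correction
  x <- c(1, 2, 2, 3, 5, 6, 6); y <- c(2, 3, 3, 4, 6, 7)
  res2 <- mann_whitney(x, y)
  expect_equal(res2$method, "tie_corrected_asymptotic")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE,
                                             exact = FALSE))
  expect_equal(res2$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(res2$U_a, unname(ref$statistic))
})

test_that("the permutation fallback approximates the exact Mann-Whitney p", {
  a <- c(5, 9, 13, 2); b <- c(7, 1, 3, 4, 8)
  p_exact <- mann_whitney(a, b, method = "exact")$p_value
  p_perm <- mann_whitney(a, b, method = "permutation", n_perm = 20000)$p_value
  expect_lt(abs(p_perm - p_exact), 0.03)
  # seeded: reproducible
  expect_equal(mann_whitney(a, b, method = "permutation")$p_value,
               mann_whitney(a, b, method = "permutation")$p_value)
})

test_that("exact Mann-Whitney keeps type-I error at or below the nominal 5%", {
  set.seed(314)
  reps <- 10000
  combos <- combn(10, 5)
  rejections <- replicate(reps, {
    x <- rnorm(10)
    r <- rank(x)
    ua_obs <- sum(r[1:5]) - 15
    ua_all <- colSums(matrix(r[combos], nrow = 5)) - 15
    p <- min(1, 2 * min(mean(ua_all <= ua_obs), mean(ua_all >= ua_obs)))
    p < 0.05
  })
  mc_slack <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(rejections), 0.05 + mc_slack)
  # spot-check that the enumerated rule above is the implementation's rule
  x <- rnorm(10)
  expect_equal(mann_whitney(x[1:5], x[6:10])$p_value, {
    r <- rank(x); ua <- sum(r[1:5]) - 15
    ua_all <- colSums(matrix(r[combos], nrow = 5)) - 15
    min(1, 2 * min(mean(ua_all <= ua), mean(ua_all >= ua)))
  })
})

test_that("Kruskal-Wallis ties out against base R and reduces to Mann-Whitney at g = 2", {
  g <- list(c(1, 5, 9, 2), c(3, 3, 7), c(8, 2, 4, 4, 6))
  res <- kruskal_wallis(g)
  ref <- stats::kruskal.test(unlist(g), factor(rep(1:3, lengths(g))))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)

  # identical constants: no variation at all
  flat <- kruskal_wallis(list(rep(4, 3), rep(4, 5)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # two groups: H = z^2, so the chi-square p equals the normal two-sided p
  set.seed(9)
  for (i in 1:10) {
    a <- sample(1:20, 9, replace = TRUE); b <- sample(5:25, 12, replace = TRUE)
    kw <- kruskal_wallis(list(a, b))
    mw <- mann_whitney(a, b, method = "asymptotic")
    expect_lt(abs(kw$p_value - mw$p_value), 1e-6)
  }
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty",
               class = "bia_validation_error")
})

test_that("Kruskal-Wallis H matches its defining formula under enumeration at n = 7", {
  # label permutations of a small pooled sample: H recomputed literally
  pool <- c(3, 1, 4, 1, 5, 9, 2)
  combos <- combn(7, 3)
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    g <- list(pool[idx], pool[-idx])
    res <- kruskal_wallis(g)
    r <- rank(pool)
    rs <- c(sum(r[idx]), sum(r[-idx]))
    h <- 12 / (7 * 8) * sum(rs^2 / c(3, 4)) - 3 * 8
    ties <- table(pool)
    h <- h / (1 - sum(ties^3 - ties) / (7^3 - 7))
    expect_equal(res$statistic, h, tolerance = 1e-12)
  }
})

test_that("Spearman handles monotone, antitone and degenerate inputs", {
  x <- c(1, 4, 9, 16, 25, 30)
  expect_equal(spearman_rank(x, sqrt(x))$statistic, 1)
  expect_equal(spearman_rank(x, -x^3)$statistic, -1)
  deg <- spearman_rank(c(2, 2, 2, 2), c(1, 5, 3, 4))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$statistic))
})

test_that("exact Spearman p equals full permutation enumeration at n = 7", {
  set.seed(41)
  perm_oracle <- function(x, y) {
    # independent enumeration: recursive permutation loop over y
    rx <- rank(x); ry <- rank(y)
    rho_obs <- cor(rx, ry)
    hits <- 0; total <- 0
    recurse <- function(remaining, acc) {
      if (length(remaining) == 0) {
        total <<- total + 1
        if (abs(cor(rx, acc)) >= abs(rho_obs) - 1e-9) hits <<- hits + 1
        return(invisible())
      }
      for (i in seq_along(remaining)) {
        recurse(remaining[-i], c(acc, remaining[i]))
      }
    }
    recurse(ry, numeric(0))
    hits / total
  }
  for (i in 1:2) {
    x <- rnorm(7); y <- rnorm(7)
    res <- spearman_rank(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, perm_oracle(x, y), tolerance = 1e-12)
  }
  # t-approximation path agrees with base R's AS 89-free approximation
  x <- rnorm(20); y <- x + rnorm(20, 0, 2)
  res <- spearman_rank(x, y)
  expect_equal(res$method, "t_approximation")
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(res$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-9)
})

test_that("rank statistics are invariant to strictly monotone transforms", {
  set.seed(55)
  a <- runif(7, 1, 9); b <- runif(6, 2, 11)
  f <- function(v) exp(v / 3) + 5
  m1 <- mann_whitney(a, b); m2 <- mann_whitney(f(a), f(b))
  expect_equal(m1$statistic, m2$statistic)
  expect_equal(m1$p_value, m2$p_value)
  cc <- runif(5)
  k1 <- kruskal_wallis(list(a, b, cc))
  k2 <- kruskal_wallis(list(f(a), f(b), f(cc)))
  expect_equal(k1$statistic, k2$statistic, tolerance = 1e-9)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(spearman_rank(x, y)$statistic,
               spearman_rank(f(x), f(y))$statistic, tolerance = 1e-12)
})
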