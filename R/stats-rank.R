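# Rank-based tests used in the assessment's group comparisons. All are
# authored here so that small-sample p-values can be exact (full
# enumeration) and the large-sample path is the tie-corrected normal /
# chi-square approximation without continuity correction, making the
# two-sample Kruskal-Wallis reduce exactly to the Mann-Whitney z-test.

bia_test_result <- function(name, statistic, p_value, method,
                            detail = list()) {
  stopifnot(p_value >= -1e-12, p_value <= 1 + 1e-12)
  structure(c(list(name = name, statistic = statistic,
                   p_value = clamp(p_value, 0, 1), method = method), detail),
            class = "bia_test_result")
}

#' @export
print.bia_test_result <- function(x, ...) {
  cat(x$name, ": statistic = ", format(x$statistic), ", p = ",
      format.pval(x$p_value, digits = 4), " [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test used to compare overall weighted scores between
#' company groups (participating vs non-participating, global vs
#' regional/national, listed vs non-listed). Ranks use midranks for ties;
#' the reported statistic is `U = min(U_a, U_b)`.
#'
#' With `method = "auto"` the two-sided p-value is exact — full enumeration
#' of the `choose(n_a + n_b, n_a)` group assignments, doubled smaller-tail
#' convention `min(1, 2 * min(P(U <= u), P(U >= u)))` — whenever
#' `min(n_a, n_b) <= exact_limit` and no tie spans the two groups; otherwise
#' the tie-corrected normal approximation (no continuity correction) is
#' used. `method = "permutation"` draws `n_perm` seeded resamples of the
#' group labels instead.
#'
#' @param a,b numeric samples.
#' @param method `"auto"`, `"exact"`, `"asymptotic"` or `"permutation"`.
#' @param exact_limit largest `min(n_a, n_b)` for the enumeration path.
#' @param n_perm number of label resamples for `method = "permutation"`.
#' @param perm_seed seed for the permutation path.
#' @return a `"bia_test_result"` with `statistic` U, `p_value`, `method`
#'   (`"exact"`, `"tie_corrected_asymptotic"` or `"permutation"`), plus
#'   `U_a`, `U_b`, `n_a`, `n_b`, `z` (asymptotic path only).
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "asymptotic",
                                          "permutation"),
                         exact_limit = 8L, n_perm = 100000L,
                         perm_seed = 20260101L) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1L, length(b) >= 1L, !anyNA(a), !anyNA(b))
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)

  ties_span_groups <- any(a %in% b)
  use_exact <- switch(method,
    auto = min(na, nb) <= exact_limit && !ties_span_groups,
    exact = TRUE, asymptotic = FALSE, permutation = FALSE)

  if (method == "permutation") {
    stat_obs <- abs(ua - na * nb / 2)
    hits <- with_seed(perm_seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, na)
        ua_p <- sum(r[idx]) - na * (na + 1) / 2
        abs(ua_p - na * nb / 2) >= stat_obs - 1e-9
      }, logical(1))
    })
    p <- mean(hits)
    return(bia_test_result("mann_whitney", u, p, "permutation",
                           list(U_a = ua, U_b = ub, n_a = na, n_b = nb,
                                n_perm = n_perm)))
  }

  if (use_exact) {
    combos <- utils::combn(n, na)
    rank_sums <- colSums(matrix(r[combos], nrow = na))
    ua_all <- rank_sums - na * (na + 1) / 2
    p_low <- mean(ua_all <= ua + 1e-9)
    p_high <- mean(ua_all >= ua - 1e-9)
    p <- min(1, 2 * min(p_low, p_high))
    return(bia_test_result("mann_whitney", u, p, "exact",
                           list(U_a = ua, U_b = ub, n_a = na, n_b = nb)))
  }

  mu <- na * nb / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- (na * nb / 12) * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(bia_test_result("mann_whitney", u, 1, "tie_corrected_asymptotic",
                           list(U_a = ua, U_b = ub, n_a = na, n_b = nb,
                                z = 0)))
  }
  z <- (ua - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  bia_test_result("mann_whitney", u, min(1, p), "tie_corrected_asymptotic",
                  list(U_a = ua, U_b = ub, n_a = na, n_b = nb, z = z))
}

#' Kruskal-Wallis rank test
#'
#' Used to examine weighted-score differences across more than two groups
#' (e.g. between expert panel members). Tie-corrected H with a chi-square
#' reference on `g - 1` degrees of freedom. When every pooled observation is
#' identical the statistic is 0 and p is 1.
#'
#' @param groups list of 2 or more numeric samples, each non-empty.
#' @return a `"bia_test_result"` with `statistic` H, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    stop_bia("Kruskal-Wallis requires every group to be non-empty",
             class = "bia_validation_error")
  }
  x <- unlist(groups, use.names = FALSE)
  stopifnot(!anyNA(x))
  n <- length(x)
  if (n < 3L) {
    stop_bia("Kruskal-Wallis requires total n >= 3",
             class = "bia_validation_error")
  }
  r <- rank(x)
  g <- rep(seq_along(groups), sizes)
  rank_sums <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  tie_tab <- table(x)
  correction <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  if (correction <= 0) {
    # all observations tied: no variation at all
    return(bia_test_result("kruskal_wallis", 0, 1,
                           "tie_corrected_asymptotic",
                           list(df = length(groups) - 1L)))
  }
  h <- h / correction
  df <- length(groups) - 1L
  p <- stats::pchisq(h, df, lower.tail = FALSE)
  bia_test_result("kruskal_wallis", h, p, "tie_corrected_asymptotic",
                  list(df = df))
}

#' Spearman rank correlation test
#'
#' Association between two quantities on the rank scale (e.g. market share
#' vs overall weighted score): `rho` is the Pearson correlation of the
#' midranks. The two-sided p-value is exact — enumeration of all `n!`
#' permutations of one rank vector, `P(|rho_perm| >= |rho_obs|)` — for
#' `n <= exact_limit`, and otherwise uses the t approximation with
#' `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric samples, `n >= 3`.
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @param exact_limit largest n for the enumeration path (default 9).
#' @return a `"bia_test_result"` with `statistic` rho, `p_value`, `n`. When
#'   either vector has zero rank variance, `rho` is `NA`, `p_value` is `NA`
#'   and the result carries `degenerate = TRUE`.
#' @export
spearman_rank <- function(x, y, method = c("auto", "exact", "asymptotic"),
                          exact_limit = 9L) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 3L, !anyNA(x), !anyNA(y))
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) <= 1e-12 || stats::var(ry) <= 1e-12) {
    res <- structure(list(name = "spearman", statistic = NA_real_,
                          p_value = NA_real_, method = "degenerate",
                          n = n, degenerate = TRUE),
                     class = "bia_test_result")
    return(res)
  }
  rho <- stats::cor(rx, ry)

  use_exact <- switch(method, auto = n <= exact_limit, exact = TRUE,
                      asymptotic = FALSE)
  if (use_exact) {
    perms <- permutations_of(n)
    rx_c <- rx - mean(rx)
    ry_c <- ry - mean(ry)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    # rho for every permutation of y's ranks against fixed x ranks
    rho_all <- as.vector(matrix(ry_c[perms], ncol = n) %*% rx_c) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-9)
    return(bia_test_result("spearman", rho, p, "exact",
                           list(n = n, degenerate = FALSE)))
  }
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  bia_test_result("spearman", rho, min(1, p), "t_approximation",
                  list(n = n, degenerate = FALSE))
}

# All permutations of 1..n as an (n! x n) index matrix.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  smaller <- permutations_of(n - 1L)
  blocks <- lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[smaller], nrow = nrow(smaller)))
  })
  out <- do.call(rbind, blocks)
  dimnames(out) <- NULL
  out
}
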