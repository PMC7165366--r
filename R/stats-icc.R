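#' Two-way random-effects absolute-agreement intraclass correlation
#'
#' Inter-rater reliability of a complete score matrix (rows = indicators or
#' subjects, columns = raters) under the two-way random-effects model with
#' absolute agreement — the convention used to gauge consistency between
#' members of an expert panel scoring the same companies. Both the
#' single-measure and average-measure variants are returned.
#'
#' From the two-way ANOVA mean squares (rows `MS_R`, columns `MS_C`,
#' residual `MS_E`, with `n` rows and `k` raters):
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' \deqn{ICC(A,k) = \frac{MS_R - MS_E}{MS_R + \frac{MS_C - MS_E}{n}}}
#'
#' 95% confidence bounds use the F-distribution construction for
#' absolute-agreement ICCs (McGraw & Wong's variance-component framework):
#' the single-measure bounds come from an F statistic with Satterthwaite
#' degrees of freedom, and average-measure bounds are the Spearman-Brown
#' transform of the single-measure bounds.
#'
#' Rows containing any `NA` are dropped listwise. A matrix with zero total
#' variance (every cell equal) is perfect agreement by convention: estimate
#' 1 with degenerate interval `[1, 1]`.
#'
#' @param m numeric matrix, rows = rated items, columns = raters.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `"bia_icc"`: `single` and `average`, each with
#'   `estimate`, `ci_low`, `ci_high`, `variant`; plus `ms` (the mean squares
#'   `MS_R`, `MS_C`, `MS_E`), `n`, `k`, `conf_level`.
#' @export
icc_two_way_random_absolute <- function(m, conf_level = 0.95) {
  stopifnot(is.matrix(m))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop_bia("ICC requires at least 2 complete rows and 2 raters (got ",
             n, " x ", k, ")", class = "bia_validation_error")
  }
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- max(ss_err, 0) / ((n - 1) * (k - 1))
  ms <- c(MS_R = msr, MS_C = msc, MS_E = mse)

  if (ss_total <= 1e-12) {
    # all cells identical: perfect agreement by convention
    res <- list(
      single = list(estimate = 1, ci_low = 1, ci_high = 1,
                    variant = "single_measure"),
      average = list(estimate = 1, ci_low = 1, ci_high = 1,
                     variant = "average_measure"),
      ms = ms, n = n, k = k, conf_level = conf_level
    )
    return(structure(res, class = "bia_icc"))
  }

  denom1 <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc1 <- if (denom1 <= 0) 1 else (msr - mse) / denom1
  denomk <- msr + (msc - mse) / n
  icck <- if (denomk <= 0) 1 else (msr - mse) / denomk
  icc1 <- clamp(icc1, -1, 1)
  icck <- clamp(icck, -1, 1)

  alpha <- 1 - conf_level
  if (mse <= 1e-300) {
    ci1 <- c(icc1, icc1)
  } else {
    r <- icc1
    a <- (k * r) / (n * (1 - r))
    b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
    if (!is.finite(a) || !is.finite(b)) {
      ci1 <- c(icc1, icc1)
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      low <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      high <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
      ci1 <- clamp(c(low, high), -1, 1)
    }
  }
  # Spearman-Brown transform of the single-measure bounds
  sb <- function(r) ifelse(is.finite(r), (k * r) / (1 + (k - 1) * r), r)
  cik <- clamp(sb(ci1), -1, 1)

  structure(list(
    single = list(estimate = icc1, ci_low = min(ci1), ci_high = max(ci1),
                  variant = "single_measure"),
    average = list(estimate = icck, ci_low = min(cik), ci_high = max(cik),
                   variant = "average_measure"),
    ms = ms, n = n, k = k, conf_level = conf_level
  ), class = "bia_icc")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
print.bia_icc <- function(x, ...) {
  fmt <- function(v) sprintf("%.3f (%d%%CI %.3f, %.3f)",
                             v$estimate, round(x$conf_level * 100),
                             v$ci_low, v$ci_high)
  cat("Two-way random absolute-agreement ICC (", x$n, " rows x ", x$k,
      " raters)\n", sep = "")
  cat("  single measure  ICC(A,1):", fmt(x$single), "\n")
  cat("  average measure ICC(A,k):", fmt(x$average), "\n")
  invisible(x)
}
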