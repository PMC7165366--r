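# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Match numeric scores to a set of band values
#'
#' Band scores are half-unit decimals (e.g. 2.5, 7.5, -10); values are
#' compared with an absolute tolerance rather than exact float equality.
#'
#' @param x numeric vector of scores.
#' @param bands numeric vector of allowed band values.
#' @param tol absolute comparison tolerance.
#' @return integer vector of indices into `bands` (`NA` where unmatched).
#' @keywords internal
match_band <- function(x, bands, tol = 1e-9) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_integer_)
    i <- which(abs(bands - v) <= tol)
    if (length(i) == 0L) NA_integer_ else i[1L]
  }, integer(1))
}

# Evaluate an expression under a fixed seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a reproducible substream seed from a root seed and a sequence of
# labels (integers or strings). Uses a multiplicative hash kept below 2^31
# so every intermediate stays exactly representable in doubles; adding a
# label never perturbs streams keyed by other labels.
substream_seed <- function(seed, ...) {
  labels <- c(...)
  h <- as.double(seed %% 2147483629)
  for (lab in labels) {
    key <- sum(utf8ToInt(as.character(lab)) * seq_along(utf8ToInt(as.character(lab))))
    h <- (h * 69069 + key * 30269 + 101) %% 2147483629
  }
  as.integer(h) + 1L
}

# Display rounding used throughout reports: percents to 1 decimal.
round1 <- function(x) round(x, 1)

stop_bia <- function(..., class) {
  stop(structure(
    class = c(class, "bia_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
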