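#' Construct and validate a market-share table
#'
#' The market-share table is the sampling frame for company selection: one
#' row per (company, food subcategory) giving the retail value and the
#' percent market share the company holds in that subcategory. Company
#' attributes (sector, scope, participation, stock-market listing) are
#' carried on every row.
#'
#' Validation enforces the structural invariants of the frame:
#' * all required columns present, enums valid, ids consistent per company;
#' * `retail_value` and `share_pct` non-negative;
#' * no duplicated (company, subcategory) pair;
#' * within each sector, shares sum to at most 100 (plus 0.5 rounding slack,
#'   since published shares are rounded to one decimal).
#'
#' @param df data.frame with columns `company_id`, `name`, `sector`,
#'   `scope`, `participating`, `listed`, `subcategory`, `retail_value`,
#'   `share_pct`.
#' @return the validated data.frame, classed `"bia_market_share"`.
#' @seealso [load_market_share_table()], [select_companies()]
#' @export
market_share_table <- function(df) {
  required <- c("company_id", "name", "sector", "scope", "participating",
                "listed", "subcategory", "retail_value", "share_pct")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_bia("market-share table is missing column(s): ",
             paste(missing, collapse = ", "), class = "bia_schema_error")
  }
  df <- as.data.frame(df)[required]
  df$company_id <- as.character(df$company_id)
  df$name <- as.character(df$name)
  df$sector <- as.character(df$sector)
  df$scope <- as.character(df$scope)
  df$subcategory <- as.character(df$subcategory)
  df$participating <- as_flag(df$participating, "participating")
  df$listed <- as_flag(df$listed, "listed")
  df$retail_value <- as.numeric(df$retail_value)
  df$share_pct <- as.numeric(df$share_pct)

  if (nrow(df) > 0L) {
    bad_sector <- !df$sector %in% bia_sectors
    if (any(bad_sector)) {
      stop_bia("invalid sector value(s): ",
               paste(unique(df$sector[bad_sector]), collapse = ", "),
               class = "bia_validation_error")
    }
    bad_scope <- !df$scope %in% bia_scopes
    if (any(bad_scope)) {
      stop_bia("invalid scope value(s): ",
               paste(unique(df$scope[bad_scope]), collapse = ", "),
               class = "bia_validation_error")
    }
    for (col in c("retail_value", "share_pct")) {
      bad <- which(is.na(df[[col]]) | df[[col]] < 0)
      if (length(bad) > 0L) {
        stop_bia("negative or missing ", col, " at row(s) ",
                 paste(utils::head(bad, 5L), collapse = ", "),
                 class = "bia_validation_error")
      }
    }
    key <- paste(df$company_id, df$subcategory, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- df[duplicated(key), , drop = FALSE]
      stop_bia("duplicated (company, subcategory) pair(s): ",
               paste(paste(dup$company_id, dup$subcategory, sep = "/"),
                     collapse = ", "),
               class = "bia_validation_error")
    }
    sector_sums <- tapply(df$share_pct, df$sector, sum)
    over <- sector_sums[sector_sums > 100 + 0.5]
    if (length(over) > 0L) {
      stop_bia("sector share sums exceed 100%: ",
               paste(names(over), round(over, 2), collapse = ", "),
               class = "bia_validation_error")
    }
    attrs <- unique(df[c("company_id", "sector", "scope", "participating", "listed", "name")])
    if (anyDuplicated(attrs$company_id)) {
      stop_bia("company attributes (sector/scope/flags/name) differ across rows ",
               "for the same company_id", class = "bia_validation_error")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("bia_market_share", "data.frame")
  df
}

as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out) && length(v) > 0L) {
    stop_bia("column '", what, "' contains non-boolean values",
             class = "bia_validation_error")
  }
  as.logical(out)
}

#' Read a market-share table from CSV
#'
#' @param path path to a CSV file with the columns documented in
#'   [market_share_table()]. An empty file with only the header yields an
#'   empty (zero-company) table.
#' @return a validated `bia_market_share` data.frame.
#' @export
load_market_share_table <- function(path) {
  if (!file.exists(path)) {
    stop_bia("file not found: ", path, class = "bia_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                        na.strings = character(0), check.names = TRUE)
  market_share_table(df)
}

#' Write a market-share table to CSV
#'
#' Writing then reading any valid table reproduces it field-for-field.
#'
#' @param table a `bia_market_share` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_market_share_table <- function(table, path) {
  stopifnot(inherits(table, "bia_market_share"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Extract the company roster from a market-share table
#'
#' One row per company with its attributes, ordered by descending total
#' share within sector.
#'
#' @param table a `bia_market_share` data.frame.
#' @return data.frame with columns `company_id`, `name`, `sector`, `scope`,
#'   `participating`, `listed`, `total_share`.
#' @export
company_roster <- function(table) {
  stopifnot(inherits(table, "bia_market_share"))
  if (nrow(table) == 0L) {
    return(data.frame(company_id = character(), name = character(),
                      sector = character(), scope = character(),
                      participating = logical(), listed = logical(),
                      total_share = numeric()))
  }
  total <- tapply(table$share_pct, table$company_id, sum)
  ros <- unique(as.data.frame(table)[c("company_id", "name", "sector", "scope",
                                       "participating", "listed")])
  ros$total_share <- as.numeric(total[ros$company_id])
  ros <- ros[order(ros$sector, -ros$total_share, ros$company_id), , drop = FALSE]
  rownames(ros) <- NULL
  ros
}

# ---------------------------------------------------------------------------
# Panel score matrices

#' Construct a panel-score matrix for one company
#'
#' Holds the independent band scores cast by each expert for each indicator.
#' Structural N/A (an indicator not applicable to the company) is encoded as
#' `NA` for *every* expert: applicability is a company property, not a rater
#' choice.
#'
#' @param company_id company identifier.
#' @param scores numeric matrix, rows = indicators (rownames = indicator
#'   ids), columns = experts (colnames = expert ids). `NA` rows mark
#'   structurally non-applicable indicators.
#' @param rubrics optional [load_indicators()] rubric set; when supplied,
#'   every non-`NA` cell must equal one of its indicator's band values.
#' @param min_panel minimum admissible panel size (the study required at
#'   least five completed scorers).
#' @return object of class `"bia_panel_scores"`.
#' @export
panel_scores <- function(company_id, scores, rubrics = NULL, min_panel = 5L) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)), !is.null(colnames(scores)))
  storage.mode(scores) <- "double"
  panel_size <- ncol(scores)
  if (panel_size < min_panel) {
    stop_bia("panel for ", company_id, " has ", panel_size,
             " expert(s); at least ", min_panel, " required",
             class = "bia_validation_error")
  }
  na_rows <- rowSums(is.na(scores))
  partial <- na_rows > 0L & na_rows < panel_size
  if (any(partial)) {
    stop_bia("N/A status inconsistent across experts for company ", company_id,
             ", indicator(s): ",
             paste(rownames(scores)[partial], collapse = ", "),
             class = "bia_validation_error")
  }
  if (!is.null(rubrics)) {
    for (ind in rownames(scores)) {
      rb <- rubrics$indicators[[ind]]
      if (is.null(rb)) {
        stop_bia("unknown indicator '", ind, "' in panel for ", company_id,
                 class = "bia_validation_error")
      }
      vals <- scores[ind, ]
      vals <- vals[!is.na(vals)]
      bad <- is.na(match_band(vals, rb$band_scores))
      if (any(bad)) {
        stop_bia("score ", paste(unique(vals[bad]), collapse = ", "),
                 " for indicator '", ind, "' (company ", company_id,
                 ") is not an allowed band; allowed bands: ",
                 paste(rb$band_scores, collapse = ", "),
                 class = "bia_validation_error")
      }
    }
  }
  structure(list(company_id = company_id, scores = scores,
                 panel_size = panel_size),
            class = "bia_panel_scores")
}

#' Read long-format panel scores
#'
#' Expects a CSV with columns `company_id, indicator_id, expert_id, score`.
#' The literal string `"NA"` marks a structurally non-applicable indicator;
#' empty score cells are rejected so silent missingness can never be
#' mistaken for structural N/A.
#'
#' @param path CSV path.
#' @param rubrics rubric set from [load_indicators()]; scores are validated
#'   against each indicator's band values.
#' @param min_panel minimum panel size (default 5).
#' @return named list of [panel_scores()] objects, one per company.
#' @export
load_panel_scores <- function(path, rubrics, min_panel = 5L) {
  if (!file.exists(path)) {
    stop_bia("file not found: ", path, class = "bia_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0), check.names = TRUE)
  required <- c("company_id", "indicator_id", "expert_id", "score")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_bia("panel-score file is missing column(s): ",
             paste(missing, collapse = ", "), class = "bia_schema_error")
  }
  if (any(trimws(df$score) == "")) {
    stop_bia("empty score cell(s) in ", path,
             "; structural N/A must be the literal string \"NA\"",
             class = "bia_validation_error")
  }
  score <- suppressWarnings(ifelse(trimws(df$score) == "NA", NA_real_,
                                   as.numeric(df$score)))
  unparsed <- which(is.na(score) & trimws(df$score) != "NA")
  if (length(unparsed) > 0L) {
    stop_bia("non-numeric score value(s) at row(s) ",
             paste(utils::head(unparsed, 5L), collapse = ", "),
             class = "bia_validation_error")
  }
  df$score_num <- score
  out <- list()
  for (cid in unique(df$company_id)) {
    sub <- df[df$company_id == cid, , drop = FALSE]
    experts <- sort(unique(sub$expert_id))
    inds <- unique(sub$indicator_id)
    key <- paste(sub$indicator_id, sub$expert_id, sep = "\r")
    if (anyDuplicated(key)) {
      stop_bia("duplicate (indicator, expert) row(s) for company ", cid,
               class = "bia_validation_error")
    }
    if (nrow(sub) != length(experts) * length(inds)) {
      stop_bia("incomplete score matrix for company ", cid,
               ": every expert must score every indicator (or N/A)",
               class = "bia_validation_error")
    }
    m <- matrix(NA_real_, nrow = length(inds), ncol = length(experts),
                dimnames = list(inds, experts))
    m[cbind(match(sub$indicator_id, inds), match(sub$expert_id, experts))] <-
      sub$score_num
    out[[cid]] <- panel_scores(cid, m, rubrics = rubrics, min_panel = min_panel)
  }
  out
}

#' Write panel scores in long format
#'
#' Inverse of [load_panel_scores()]: structural `NA` cells are written as
#' the literal token `"NA"`.
#'
#' @param panels named list of `bia_panel_scores` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_scores <- function(panels, path) {
  rows <- lapply(panels, function(p) {
    m <- p$scores
    data.frame(
      company_id = p$company_id,
      indicator_id = rep(rownames(m), times = ncol(m)),
      expert_id = rep(colnames(m), each = nrow(m)),
      score = ifelse(is.na(as.vector(m)), "NA",
                     format(as.vector(m), trim = TRUE, scientific = FALSE)),
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Domain weights

#' Read sector domain weights
#'
#' The weight file is YAML with a `version` field and a `weights` mapping
#' `sector -> domain -> weight`. For every sector the six domain weights
#' must sum to exactly 100; a file failing this is rejected outright, never
#' renormalised (renormalisation is reserved for per-company N/A domains at
#' scoring time, see [overall_weighted_score()]).
#'
#' @param path YAML path.
#' @return named list (class `"bia_weights"`): sector -> named numeric
#'   vector over [bia_domains].
#' @export
load_weights <- function(path) {
  if (!file.exists(path)) {
    stop_bia("file not found: ", path, class = "bia_io_error")
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$version) || is.null(doc$weights)) {
    stop_bia("weights file must have 'version' and 'weights' fields",
             class = "bia_schema_error")
  }
  out <- list()
  for (sector in names(doc$weights)) {
    if (!sector %in% bia_sectors) {
      stop_bia("unknown sector '", sector, "' in weights file",
               class = "bia_validation_error")
    }
    w <- unlist(doc$weights[[sector]])
    missing <- setdiff(bia_domains, names(w))
    if (length(missing) > 0L) {
      stop_bia("sector '", sector, "' is missing weight(s) for: ",
               paste(missing, collapse = ", "), class = "bia_schema_error")
    }
    w <- w[bia_domains]
    if (any(w < 0)) {
      stop_bia("negative weight(s) for sector '", sector, "'",
               class = "bia_validation_error")
    }
    if (abs(sum(w) - 100) > 1e-9) {
      stop_bia("weights for sector '", sector, "' sum to ", sum(w),
               ", not 100; weights are never renormalised at load time",
               class = "bia_validation_error")
    }
    out[[sector]] <- w
  }
  structure(out, class = "bia_weights")
}

#' Build a weights object in code
#'
#' @param ... named arguments, one per sector, each a named numeric vector
#'   over the six domains summing to 100.
#' @return object of class `"bia_weights"`.
#' @export
domain_weights <- function(...) {
  ws <- list(...)
  out <- list()
  for (sector in names(ws)) {
    stopifnot(sector %in% bia_sectors)
    w <- ws[[sector]][bia_domains]
    if (anyNA(w)) {
      stop_bia("sector '", sector, "' is missing domain weight(s)",
               class = "bia_schema_error")
    }
    if (abs(sum(w) - 100) > 1e-9) {
      stop_bia("weights for sector '", sector, "' must sum to 100",
               class = "bia_validation_error")
    }
    out[[sector]] <- w
  }
  structure(out, class = "bia_weights")
}
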