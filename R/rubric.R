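#' Read an indicator rubric set
#'
#' The rubric file is YAML with four parts:
#'
#' * `version`: schema version string.
#' * `attributes`: the evidence schema — every attribute a band predicate
#'   may reference, with its type (`enum` + `values`, `boolean`, or
#'   `integer` + `min`/`max`).
#' * `flags`: the portfolio-flag schema used by applicability predicates
#'   (e.g. `sells_food`), in the same format.
#' * `indicators`: one entry per indicator with `id`, `domain` (one of
#'   [bia_domains]), `question`, optional `status`, optional `applicability`
#'   predicate, and an ordered list of `bands`, each `score` + `label` +
#'   either a `when` map, an `any_of` list of maps, or `default: true`.
#'
#' A predicate `when` map is a conjunction over attributes; each condition
#' is a scalar (equality), a list (set membership), or a `min`/`max` map for
#' integer attributes. `any_of` is a disjunction of such maps. Exactly one
#' band per indicator must be the `default` floor (matched when nothing else
#' is); deficit bands (negative scores) carry explicit predicates and are
#' therefore tested before the floor.
#'
#' Load-time validation asserts: distinct band scores within `[-10, 10]`, a
#' floor band with score `<= 0`, every predicate attribute declared in the
#' schema, and mutual exclusivity of the explicit band predicates (checked
#' by exhaustive enumeration of the attribute grid), which makes band
#' selection order-independent.
#'
#' @param path YAML path.
#' @return object of class `"bia_rubric_set"`: `version`, `attributes`,
#'   `flags`, and `indicators` (named list of `"bia_rubric"` objects).
#' @export
load_indicators <- function(path) {
  if (!file.exists(path)) {
    stop_bia("file not found: ", path, class = "bia_io_error")
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$version) || is.null(doc$indicators) || is.null(doc$attributes)) {
    stop_bia("indicator file must have 'version', 'attributes' and 'indicators'",
             class = "bia_schema_error")
  }
  attrs <- doc$attributes
  flags <- doc$flags %||% list()
  indicators <- list()
  for (spec in doc$indicators) {
    rb <- build_rubric(spec, attrs, flags)
    if (!is.null(indicators[[rb$indicator_id]])) {
      stop_bia("duplicate indicator id '", rb$indicator_id, "'",
               class = "bia_validation_error")
    }
    indicators[[rb$indicator_id]] <- rb
  }
  structure(list(version = doc$version, attributes = attrs, flags = flags,
                 indicators = indicators),
            class = "bia_rubric_set")
}

build_rubric <- function(spec, attr_schema, flag_schema) {
  for (field in c("id", "domain", "question", "bands")) {
    if (is.null(spec[[field]])) {
      stop_bia("indicator entry is missing field '", field, "'",
               class = "bia_schema_error")
    }
  }
  if (!spec$domain %in% bia_domains) {
    stop_bia("indicator '", spec$id, "': unknown domain '", spec$domain, "'",
             class = "bia_validation_error")
  }
  bands <- lapply(spec$bands, function(b) {
    if (is.null(b$score)) {
      stop_bia("indicator '", spec$id, "': band without a score",
               class = "bia_schema_error")
    }
    list(score = as.numeric(b$score), label = b$label %||% "",
         when = b$when, any_of = b$any_of, default = isTRUE(b$default))
  })
  scores <- vapply(bands, `[[`, numeric(1), "score")
  if (anyDuplicated(scores)) {
    stop_bia("indicator '", spec$id, "': duplicate band scores",
             class = "bia_validation_error")
  }
  if (any(scores < -10 | scores > 10)) {
    stop_bia("indicator '", spec$id, "': band scores must lie in [-10, 10]",
             class = "bia_validation_error")
  }
  if (!any(scores <= 0)) {
    stop_bia("indicator '", spec$id, "': no floor band (score 0 or negative)",
             class = "bia_validation_error")
  }
  n_default <- sum(vapply(bands, `[[`, logical(1), "default"))
  if (n_default != 1L) {
    stop_bia("indicator '", spec$id, "': exactly one band must be default: true",
             class = "bia_validation_error")
  }
  default_score <- scores[vapply(bands, `[[`, logical(1), "default")]
  if (default_score > 0) {
    stop_bia("indicator '", spec$id, "': the default floor band must score <= 0",
             class = "bia_validation_error")
  }
  # predicate attributes must be declared in the evidence schema
  used <- unlist(lapply(bands, predicate_attrs))
  undeclared <- setdiff(used, names(attr_schema))
  if (length(undeclared) > 0L) {
    stop_bia("indicator '", spec$id, "': predicate references undeclared ",
             "attribute(s): ", paste(undeclared, collapse = ", "),
             class = "bia_config_error")
  }
  if (!is.null(spec$applicability)) {
    app_used <- predicate_attrs(list(when = spec$applicability$when,
                                     any_of = spec$applicability$any_of))
    known <- c(names(flag_schema), "sector", "scope", "participating", "listed")
    bad <- setdiff(app_used, known)
    if (length(bad) > 0L) {
      stop_bia("indicator '", spec$id, "': applicability references undeclared ",
               "flag(s): ", paste(bad, collapse = ", "),
               class = "bia_config_error")
    }
  }
  rb <- structure(list(
    indicator_id = spec$id,
    domain = spec$domain,
    question = spec$question,
    status = spec$status %||% "example",
    applicability = spec$applicability,
    bands = bands,
    band_scores = sort(scores),
    max_score = max(scores),
    default_score = default_score
  ), class = "bia_rubric")
  check_band_exclusivity(rb, attr_schema)
  rb
}

predicate_attrs <- function(band) {
  c(names(band$when), unlist(lapply(band$any_of, names)))
}

# Enumerate the attribute grid touched by an indicator's explicit band
# predicates and assert no two bands can match the same evidence; this is
# what licenses order-independent band selection.
check_band_exclusivity <- function(rubric, attr_schema, max_grid = 250000L) {
  explicit <- Filter(function(b) !b$default, rubric$bands)
  used <- unique(unlist(lapply(explicit, predicate_attrs)))
  if (length(used) == 0L) return(invisible(TRUE))
  values <- lapply(used, function(a) attr_domain_values(attr_schema[[a]], a))
  names(values) <- used
  n_grid <- prod(vapply(values, length, numeric(1)))
  if (n_grid > max_grid) {
    stop_bia("indicator '", rubric$indicator_id,
             "': attribute grid too large to verify band exclusivity",
             class = "bia_config_error")
  }
  grid <- expand.grid(lapply(values, seq_along))
  for (i in seq_len(nrow(grid))) {
    ev <- lapply(used, function(a) values[[a]][[grid[i, a]]])
    names(ev) <- used
    ev <- ev[!vapply(ev, function(v) identical(v, "__absent__"), logical(1))]
    hits <- vapply(explicit, function(b) band_matches(b, ev), logical(1))
    if (sum(hits) > 1L) {
      stop_bia("indicator '", rubric$indicator_id,
               "': bands are not mutually exclusive (evidence ",
               paste(names(ev), unlist(ev), sep = "=", collapse = ", "),
               " matches ", sum(hits), " bands)",
               class = "bia_config_error")
    }
  }
  invisible(TRUE)
}

attr_domain_values <- function(schema, name) {
  if (is.null(schema)) {
    stop_bia("attribute '", name, "' missing from schema",
             class = "bia_config_error")
  }
  vals <- switch(schema$type,
    enum = schema$values,
    boolean = list(TRUE, FALSE),
    integer = as.list(seq(schema$min %||% 0L, schema$max %||% 25L)),
    stop_bia("attribute '", name, "': unknown type '", schema$type, "'",
             class = "bia_config_error")
  )
  c(vals, "__absent__")
}

# ---------------------------------------------------------------------------
# Predicate evaluation

cond_holds <- function(cond, val) {
  if (is.null(val) || (length(val) == 1L && is.na(val))) return(FALSE)
  if (identical(val, "unknown")) return(FALSE)
  if (is.list(cond) && (!is.null(cond$min) || !is.null(cond$max))) {
    if (!is.numeric(val)) return(FALSE)
    ok <- TRUE
    if (!is.null(cond$min)) ok <- ok && val >= cond$min
    if (!is.null(cond$max)) ok <- ok && val <= cond$max
    return(ok)
  }
  allowed <- unlist(cond, use.names = FALSE)
  if (is.numeric(allowed) && is.numeric(val)) {
    return(any(abs(allowed - val) <= 1e-9))
  }
  val %in% allowed
}

when_holds <- function(when, attrs) {
  all(vapply(names(when), function(k) cond_holds(when[[k]], attrs[[k]]),
             logical(1)))
}

band_matches <- function(band, attrs) {
  if (!is.null(band$any_of)) {
    return(any(vapply(band$any_of, when_holds, logical(1), attrs = attrs)))
  }
  if (!is.null(band$when)) return(when_holds(band$when, attrs))
  FALSE
}

#' Score one indicator from coded evidence
#'
#' Evidence enters as a named list of structured attributes (never free
#' text); bands with explicit predicates are evaluated in descending score
#' order and the first satisfied band wins. If no explicit band matches —
#' including the all-absent, no-evidence case — the rubric's default floor
#' band scores. Absent attributes and the value `"unknown"` both fail any
#' condition that references them.
#'
#' @param evidence named list of attribute values for this indicator.
#' @param rubric a `"bia_rubric"` object.
#' @param attr_schema optional evidence schema (from the rubric set); when
#'   supplied, evidence attributes are validated against it.
#' @return the numeric band score.
#' @examples
#' \dontrun{
#' rubrics <- load_indicators(system.file("extdata", "indicators.yaml",
#'                                        package = "biaobesity"))
#' score_indicator(list(commitment_level = "national",
#'                      publicly_available = TRUE),
#'                 rubrics$indicators$cs_overarching_commitment)
#' }
#' @export
score_indicator <- function(evidence, rubric, attr_schema = NULL) {
  stopifnot(inherits(rubric, "bia_rubric"))
  evidence <- evidence %||% list()
  if (!is.null(attr_schema)) {
    validate_evidence_attrs(evidence, attr_schema, rubric$indicator_id)
  }
  explicit <- Filter(function(b) !b$default, rubric$bands)
  ord <- order(vapply(explicit, `[[`, numeric(1), "score"), decreasing = TRUE)
  for (b in explicit[ord]) {
    if (band_matches(b, evidence)) return(b$score)
  }
  rubric$default_score
}

validate_evidence_attrs <- function(evidence, attr_schema, indicator_id) {
  undeclared <- setdiff(names(evidence), names(attr_schema))
  if (length(undeclared) > 0L) {
    stop_bia("evidence for indicator '", indicator_id,
             "' uses undeclared attribute(s): ",
             paste(undeclared, collapse = ", "), class = "bia_validation_error")
  }
  for (a in names(evidence)) {
    v <- evidence[[a]]
    if (is.null(v) || identical(v, "unknown")) next
    sch <- attr_schema[[a]]
    ok <- switch(sch$type,
      enum = v %in% unlist(sch$values),
      boolean = is.logical(v),
      integer = is.numeric(v) && v == round(v),
      FALSE)
    if (!ok) {
      stop_bia("evidence value '", v, "' invalid for attribute '", a,
               "' (", sch$type, ")", class = "bia_validation_error")
    }
  }
  invisible(TRUE)
}

#' Determine which indicators apply to a company
#'
#' Indicator applicability is a company property: an applicability predicate
#' is evaluated over the company's roster attributes (`sector`, `scope`,
#' `participating`, `listed`) merged with its declared portfolio flags
#' (e.g. `sells_food = FALSE` for a beverage-only manufacturer). Indicators
#' without an applicability predicate apply to every company. A flag missing
#' from `portfolio_flags` fails any condition that references it.
#'
#' @param company one-row data.frame or named list with the roster fields.
#' @param portfolio_flags named list of product-portfolio facts.
#' @param rubrics a `"bia_rubric_set"`.
#' @return character vector of applicable indicator ids.
#' @export
applicable_indicators <- function(company, portfolio_flags, rubrics) {
  stopifnot(inherits(rubrics, "bia_rubric_set"))
  attrs <- c(as.list(company)[c("sector", "scope", "participating", "listed")],
             portfolio_flags %||% list())
  ids <- names(rubrics$indicators)
  keep <- vapply(ids, function(id) {
    app <- rubrics$indicators[[id]]$applicability
    if (is.null(app)) return(TRUE)
    band_matches(list(when = app$when, any_of = app$any_of, default = FALSE),
                 attrs)
  }, logical(1))
  ids[keep]
}

#' Score a company's full evidence map
#'
#' @param evidence_map named list `indicator_id -> evidence attribute list`.
#' @param rubrics a `"bia_rubric_set"`.
#' @param applicable character vector of applicable indicator ids (from
#'   [applicable_indicators()]); others are returned as `NA` (structural
#'   N/A). Defaults to all indicators.
#' @return named numeric vector over all indicators in the set.
#' @export
score_company_evidence <- function(evidence_map, rubrics,
                                   applicable = names(rubrics$indicators)) {
  stopifnot(inherits(rubrics, "bia_rubric_set"))
  out <- vapply(names(rubrics$indicators), function(id) {
    if (!id %in% applicable) return(NA_real_)
    score_indicator(evidence_map[[id]] %||% list(), rubrics$indicators[[id]],
                    attr_schema = rubrics$attributes)
  }, numeric(1))
  names(out) <- names(rubrics$indicators)
  out
}

#' Read a per-company evidence file
#'
#' YAML mapping `company_id -> indicator_id -> attribute map`, validated
#' against the rubric set's evidence schema.
#'
#' @param path YAML path.
#' @param rubrics a `"bia_rubric_set"`.
#' @return named list of evidence maps.
#' @export
load_evidence <- function(path, rubrics) {
  if (!file.exists(path)) {
    stop_bia("file not found: ", path, class = "bia_io_error")
  }
  doc <- yaml::read_yaml(path)
  for (cid in names(doc)) {
    for (ind in names(doc[[cid]])) {
      if (is.null(rubrics$indicators[[ind]])) {
        stop_bia("evidence for ", cid, " references unknown indicator '",
                 ind, "'", class = "bia_validation_error")
      }
      validate_evidence_attrs(doc[[cid]][[ind]], rubrics$attributes, ind)
    }
  }
  doc
}
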