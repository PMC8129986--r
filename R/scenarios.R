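#' Define one prioritization scenario
#'
#' A scenario is one cell of the sensitivity matrix: an enabling-condition
#' filter (or none), a benefit field, and a threat-classification scheme.
#'
#' @param filter A [filter_rule], a conjunction, or `NULL` for no screening.
#' @param benefit_field Benefit column name.
#' @param scheme_id Id of the classification scheme to use.
#' @param top_k Size of the solution set extracted from the ranking
#'   (default 10).
#' @param filter_label Label used in the auto-generated scenario id; defaults
#'   to the filter's label, or `"all"` when `filter` is `NULL`.
#' @param scenario_id Override for the auto id
#'   `"<filter>|<benefit>|<scheme>"`.
#' @param p_source,c_source Passed to [score_pool()].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(filter, benefit_field, scheme_id, top_k = 10,
                          filter_label = NULL, scenario_id = NULL,
                          p_source = "constant_one", c_source = "constant_one") {
  if (!is.null(filter) && !inherits(filter, "filter_rule")) {
    stop_validation("scenario: 'filter' must be NULL or a filter_rule")
  }
  if (!is_string(benefit_field)) stop_validation("scenario: benefit_field must be a string")
  if (!is_string(scheme_id)) stop_validation("scenario: scheme_id must be a string")
  if (!is_count(top_k)) stop_validation("scenario: top_k must be a positive integer")
  if (is.null(filter_label)) {
    filter_label <- if (is.null(filter)) "all" else filter$label
  }
  if (is.null(scenario_id)) {
    scenario_id <- paste(filter_label, benefit_field, scheme_id, sep = "|")
  }
  structure(list(scenario_id = scenario_id, filter = filter,
                 filter_label = filter_label, benefit_field = benefit_field,
                 scheme_id = scheme_id, top_k = as.integer(top_k),
                 p_source = p_source, c_source = c_source),
            class = "scenario_spec")
}

#' Build the full scenario matrix
#'
#' Cartesian product of filters x benefit fields x schemes, in deterministic
#' order (filters outermost, schemes innermost). The shipped default design
#' is 4 filters (none, debt-to-GDP >= 0.40 / 0.60 / 0.80) x 2 benefits (EEZ
#' area, coral area) x 2 schemes (shipping abatable / unabatable) = 16
#' scenarios; see [default_debt_filters()].
#'
#' @param filters Named list of filters (`NULL` entries mean no screening;
#'   names become the filter part of scenario ids, falling back to rule
#'   labels).
#' @param benefit_fields Character vector of benefit column names.
#' @param scheme_ids Character vector of scheme ids.
#' @param top_k Solution-set size applied to every scenario.
#' @param p_source,c_source Passed to every scenario.
#' @return List of [scenario_spec] objects of length
#'   `length(filters) * length(benefit_fields) * length(scheme_ids)`.
#' @export
build_matrix <- function(filters, benefit_fields, scheme_ids, top_k = 10,
                         p_source = "constant_one", c_source = "constant_one") {
  if (length(filters) == 0L || length(benefit_fields) == 0L || length(scheme_ids) == 0L) {
    stop_validation("build_matrix: filters, benefit_fields and scheme_ids must be non-empty")
  }
  if (!is.list(filters)) filters <- list(filters)
  labels <- names(filters)
  if (is.null(labels)) labels <- rep("", length(filters))
  specs <- list()
  for (i in seq_along(filters)) {
    f <- filters[[i]]
    lab <- if (nzchar(labels[i])) labels[i] else if (is.null(f)) "all" else f$label
    for (b in benefit_fields) {
      for (s in scheme_ids) {
        specs[[length(specs) + 1L]] <-
          scenario_spec(f, b, s, top_k = top_k, filter_label = lab,
                        p_source = p_source, c_source = c_source)
      }
    }
  }
  ids <- vapply(specs, `[[`, "", "scenario_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop_validation("build_matrix: duplicate scenario id(s): %s", paste(dup, collapse = ", "))
  }
  specs
}

#' The default enabling-condition filter set
#'
#' No screening plus the three inclusive debt-to-GDP thresholds (>= 40%,
#' >= 60%, >= 80%) used to probe sensitivity of priorities to the enabling
#' condition.
#'
#' @return Named list of filters suitable for [build_matrix()].
#' @export
default_debt_filters <- function() {
  list(all = NULL,
       ge40 = filter_rule("debt_to_gdp", "ge", 0.40),
       ge60 = filter_rule("debt_to_gdp", "ge", 0.60),
       ge80 = filter_rule("debt_to_gdp", "ge", 0.80))
}

#' Compute shared alpha parameters over the full candidate pool
#'
#' One alpha per classification scheme, each derived from the full loaded
#' candidate pool (`alpha = 1/max(i_unabatable)`), so that expected benefits
#' are comparable across all filter and benefit scenarios that share a
#' scheme. The maximum unabatable burden is scheme-dependent (moving a layer
#' such as shipping into the unabatable class raises it), so alphas cannot
#' be shared across schemes without breaking the non-negativity guarantee.
#'
#' @param countries A [country_table] (the full pool).
#' @param layers A [threat_table].
#' @param schemes Named list of [classification_scheme] objects.
#' @return Named list of `alpha_parameter` objects, one per scheme id.
#' @export
pool_alphas <- function(countries, layers, schemes) {
  stopifnot(inherits(countries, "country_table"))
  out <- list()
  for (sc in schemes) {
    stopifnot(inherits(sc, "classification_scheme"))
    s <- summarize_threats(layers, sc, countries$country_id)
    out[[sc$scheme_id]] <- compute_alpha(s, "pool_max_reciprocal",
                                         pool_id = "full_pool")
  }
  out
}

#' Run one scenario end to end
#'
#' Screening, threat summaries under the scenario's scheme, scoring with the
#' shared alpha, ranking, and top-k extraction. An empty post-screening pool
#' yields an empty ranking with a warning, not an error.
#'
#' @param spec A [scenario_spec].
#' @param countries Full [country_table].
#' @param layers A [threat_table].
#' @param schemes Named list of [classification_scheme] objects (must
#'   contain `spec$scheme_id`).
#' @param alphas Named list from [pool_alphas()] giving the shared alpha per
#'   scheme, or `NULL` to recompute alpha over this scenario's own
#'   post-screening pool (the per-scenario switch).
#' @return An object of class `scenario_result`: list with `scenario_id`,
#'   `scheme_id`, `benefit_field`, `alpha_used`, `pool_size`, `top_k`,
#'   `scored` (ranked `scored_pool`), `top_k_set`, `screened_out`.
#' @export
run_scenario <- function(spec, countries, layers, schemes, alphas = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(countries, "country_table"))
  scheme <- schemes[[spec$scheme_id]]
  if (is.null(scheme)) stop_validation("unknown scheme id '%s'", spec$scheme_id)
  if (is.null(spec$filter)) {
    pool_ids <- countries$country_id
    screened_out <- stats::setNames(character(0), character(0))
  } else {
    scr <- apply_rule(countries, spec$filter)
    pool_ids <- scr$passed
    screened_out <- scr$excluded
  }
  if (length(pool_ids) == 0L) {
    warning(sprintf("scenario '%s': no candidates pass screening", spec$scenario_id))
    empty <- rank_pool(data.frame(country_id = character(0), ce_score = numeric(0)))
    return(structure(list(scenario_id = spec$scenario_id, scheme_id = spec$scheme_id,
                          benefit_field = spec$benefit_field, alpha_used = NA_real_,
                          pool_size = 0L, top_k = spec$top_k, scored = empty,
                          top_k_set = character(0), screened_out = screened_out),
                     class = "scenario_result"))
  }
  summaries <- summarize_threats(layers, scheme, pool_ids)
  alpha <- if (is.null(alphas)) {
    compute_alpha(summaries, "pool_max_reciprocal", pool_id = spec$scenario_id)
  } else {
    a <- alphas[[spec$scheme_id]]
    if (is.null(a)) stop_validation("no shared alpha for scheme '%s'", spec$scheme_id)
    a
  }
  pool <- countries[match(pool_ids, countries$country_id), , drop = FALSE]
  class(pool) <- class(countries)
  scored <- score_pool(pool, summaries, alpha, spec$benefit_field,
                       p_source = spec$p_source, c_source = spec$c_source)
  k <- min(spec$top_k, nrow(scored))
  structure(list(scenario_id = spec$scenario_id, scheme_id = spec$scheme_id,
                 benefit_field = spec$benefit_field, alpha_used = alpha$value,
                 pool_size = nrow(scored), top_k = spec$top_k, scored = scored,
                 top_k_set = scored$country_id[seq_len(k)],
                 screened_out = screened_out),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, n = 5L, ...) {
  cat(sprintf("Scenario %s\n  alpha = %.4g, pool = %d, top-%d set: %s\n",
              x$scenario_id, x$alpha_used, x$pool_size, x$top_k,
              paste(utils::head(x$top_k_set, n), collapse = ", ")))
  invisible(x)
}

#' Run every scenario of a matrix
#'
#' Scenarios are independent: each result depends only on its own spec and
#' the shared inputs, and results are returned in spec order. A failure in
#' any scenario aborts the whole run with the scenario id attached — no
#' partial silent output.
#'
#' @param specs List of [scenario_spec] objects.
#' @inheritParams run_scenario
#' @return List of `scenario_result` objects, same order as `specs`.
#' @export
run_all <- function(specs, countries, layers, schemes, alphas = NULL) {
  lapply(specs, function(sp) {
    tryCatch(run_scenario(sp, countries, layers, schemes, alphas),
             error = function(e) {
               stop(sprintf("scenario '%s': %s", sp$scenario_id, conditionMessage(e)),
                    call. = FALSE)
             })
  })
}
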