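#' Define an enabling-condition screening rule
#'
#' Screening filters the candidate pool by enabling conditions — economic,
#' governance or political circumstances a country must meet before a debt
#' conversion is worth pursuing (the canonical example: debt-to-GDP ratio of
#' 60% or higher). Rules are simple threshold or flag tests on country-table
#' columns; they are combined only conjunctively (see [compose_rules()]) —
#' a structured decision tree, deliberately not a weighted score.
#'
#' @param field Name of a country-table column (core field or extra).
#' @param op One of `"ge"`, `"le"`, `"eq"` (numeric comparisons, inclusive),
#'   `"is_true"`, `"is_false"` (flags).
#' @param threshold Numeric threshold; required for `ge`/`le`/`eq`, absent
#'   for the flag operators.
#' @param label Human-readable label used in exclusion annotations; a
#'   default is derived from the rule.
#' @return An object of class `filter_rule`.
#' @examples
#' filter_rule("debt_to_gdp", "ge", 0.6)
#' @export
filter_rule <- function(field, op = c("ge", "le", "eq", "is_true", "is_false"),
                        threshold = NULL, label = NULL) {
  op <- match.arg(op)
  if (!is_string(field)) stop_validation("filter rule: 'field' must be a single string")
  if (op %in% c("ge", "le", "eq")) {
    if (is.null(threshold) || !is.numeric(threshold) || length(threshold) != 1L ||
        !is.finite(threshold)) {
      stop_validation("filter rule on '%s': operator '%s' needs a finite numeric threshold",
                      field, op)
    }
  } else if (!is.null(threshold)) {
    stop_validation("filter rule on '%s': operator '%s' takes no threshold", field, op)
  }
  if (is.null(label)) {
    label <- switch(op,
      ge = sprintf("%s >= %g", field, threshold),
      le = sprintf("%s <= %g", field, threshold),
      eq = sprintf("%s == %g", field, threshold),
      is_true = sprintf("%s is TRUE", field),
      is_false = sprintf("%s is FALSE", field))
  }
  structure(list(field = field, op = op, threshold = threshold, label = label),
            class = "filter_rule")
}

#' Combine screening rules conjunctively
#'
#' A candidate passes the composite rule iff it passes every component rule;
#' exclusion annotations cite the first failing rule in list order. No
#' disjunction or weighting is offered: scoring and weighting enabling
#' conditions in ad-hoc ways is exactly what a screening step should avoid,
#' and alternative conditions are better explored as separate scenarios.
#'
#' @param rules Non-empty list of [filter_rule] objects.
#' @return A `filter_rule` of subclass `rule_conjunction`.
#' @export
compose_rules <- function(rules) {
  if (inherits(rules, "filter_rule")) rules <- list(rules)
  if (!is.list(rules) || length(rules) == 0L) {
    stop_validation("compose_rules: need a non-empty list of rules")
  }
  flat <- list()
  for (r in rules) {
    if (!inherits(r, "filter_rule")) stop_validation("compose_rules: not a filter_rule")
    flat <- c(flat, if (inherits(r, "rule_conjunction")) r$rules else list(r))
  }
  structure(list(rules = flat,
                 label = paste(vapply(flat, `[[`, "", "label"), collapse = " AND ")),
            class = c("rule_conjunction", "filter_rule"))
}

# Logical pass vector for one elementary rule over a country table.
rule_passes <- function(records, rule) {
  x <- records[[rule$field]]
  if (is.null(x)) {
    stop_validation("screening: unknown field '%s' (rule '%s')", rule$field, rule$label)
  }
  if (anyNA(x)) {
    stop_validation("screening: field '%s' has missing values for: %s",
                    rule$field,
                    paste(records$country_id[is.na(x)], collapse = ", "))
  }
  if (rule$op %in% c("is_true", "is_false")) {
    if (is.numeric(x) && all(x %in% c(0, 1))) x <- as.logical(x)
    if (!is.logical(x)) {
      stop_validation("screening: field '%s' is not boolean but rule '%s' expects a flag",
                      rule$field, rule$label)
    }
    if (rule$op == "is_true") x else !x
  } else {
    if (!is.numeric(x)) {
      stop_validation("screening: field '%s' is not numeric but rule '%s' compares numerically",
                      rule$field, rule$label)
    }
    switch(rule$op,
           ge = x >= rule$threshold,
           le = x <= rule$threshold,
           eq = x == rule$threshold)
  }
}

#' Apply a screening rule to a candidate pool
#'
#' @param records A [country_table].
#' @param rule A [filter_rule] or conjunction from [compose_rules()].
#' @return An object of class `screening_result`: list with `rule_labels`
#'   (applied rules in order), `passed` (country ids in input order) and
#'   `excluded` (named character vector mapping excluded country ids to the
#'   label of the first failing rule).
#' @examples
#' ct <- country_table(data.frame(
#'   country_id = c("AAA", "BBB"), debt_to_gdp = c(0.5, 0.7),
#'   eez_area_km2 = 1, coral_area_km2 = 1))
#' apply_rule(ct, filter_rule("debt_to_gdp", "ge", 0.6))$passed
#' @export
apply_rule <- function(records, rule) {
  stopifnot(inherits(records, "country_table"))
  if (!inherits(rule, "filter_rule")) stop_validation("apply_rule: not a filter_rule")
  rules <- if (inherits(rule, "rule_conjunction")) rule$rules else list(rule)
  ids <- records$country_id
  first_fail <- rep(NA_character_, length(ids))
  for (r in rules) {
    ok <- rule_passes(records, r)
    newly <- !ok & is.na(first_fail)
    first_fail[newly] <- r$label
  }
  passed <- ids[is.na(first_fail)]
  excluded <- stats::setNames(first_fail[!is.na(first_fail)], ids[!is.na(first_fail)])
  structure(list(rule_labels = vapply(rules, `[[`, "", "label"),
                 passed = passed, excluded = excluded),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Screening:", paste(x$rule_labels, collapse = " AND "), "\n")
  cat(sprintf("  passed: %d, excluded: %d\n", length(x$passed), length(x$excluded)))
  invisible(x)
}
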