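#' Threat-adjusted expected benefit
#'
#' The core quantity of the prioritization: the biodiversity benefit `b`
#' (e.g. EEZ or coral-reef area in km2) weighted by the abatable threat
#' burden `i_a` (how much threat the action can actually remove) and
#' discounted by the unabatable burden through `(1 - alpha * i_u)`:
#'
#'   expected benefit = b * i_a * (1 - alpha * i_u)
#'
#' A country with no abatable threat scores 0 — there is nothing a marine
#' protected area could abate — as does the country at the pool's maximum
#' unabatable burden when alpha is the pool-max reciprocal.
#'
#' @param b Benefit value(s), finite and >= 0.
#' @param i_a Abatable burden(s), finite and >= 0.
#' @param i_u Unabatable burden(s), finite and >= 0.
#' @param alpha An [compute_alpha()] result (`alpha_parameter`).
#' @return Numeric vector of expected benefits (same units as `b`).
#' @examples
#' a <- structure(list(value = 0.18, policy = "fixed", pool_id = "p",
#'                     max_iu = 1/0.18), class = "alpha_parameter")
#' expected_benefit(100, 0.5, 3, a)  # 100 * 0.5 * (1 - 0.54) = 23
#' @export
expected_benefit <- function(b, i_a, i_u, alpha) {
  for (nm in c("b", "i_a", "i_u")) {
    v <- get(nm)
    if (any(!is.finite(v) | v < 0)) {
      stop_validation("expected_benefit: '%s' must be finite and >= 0", nm)
    }
  }
  b * i_a * discount_factor(i_u, alpha)
}

#' Threat-adjusted cost-effectiveness score
#'
#' Expected benefit times the probability of success, divided by cost:
#' `b * i_a * (1 - alpha * i_u) * p / c`. With `p = c = 1` (the default when
#' no credible estimates exist across candidates) the score reduces to the
#' expected benefit and priorities are driven solely by benefit and threat.
#'
#' @inheritParams expected_benefit
#' @param p_success Probability the action succeeds, in \[0, 1\].
#' @param cost Positive cost in consistent units.
#' @return Numeric vector of scores.
#' @export
ce_score <- function(b, i_a, i_u, alpha, p_success = 1, cost = 1) {
  if (any(!is.finite(p_success) | p_success < 0 | p_success > 1)) {
    stop_validation("ce_score: p_success must be in [0,1]")
  }
  if (any(!is.finite(cost) | cost <= 0)) stop_validation("ce_score: cost must be > 0")
  expected_benefit(b, i_a, i_u, alpha) * p_success / cost
}

#' Score a candidate pool under one benefit field and threat scheme
#'
#' Joins a country table with its threat summaries, evaluates the
#' cost-effectiveness score for the chosen benefit field, and returns the
#' ranked pool. Scores are carried at full floating precision; rounding
#' happens only in [write_results()].
#'
#' @param countries A [country_table] restricted to the pool (or a superset;
#'   only countries present in `summaries` are scored).
#' @param summaries Threat summaries from [summarize_threats()] for the pool.
#' @param alpha An `alpha_parameter` guarding (at least) this pool.
#' @param benefit_field Name of the benefit column (e.g. `"eez_area_km2"`).
#' @param p_source,c_source `"constant_one"` (default; probability of
#'   success and cost fixed at 1) or `"column"` (use the table's
#'   `p_success`/`cost` columns).
#' @return Data frame of class `scored_pool` with columns `rank`,
#'   `country_id`, `b`, `i_abatable`, `i_unabatable`, `discount`,
#'   `expected_benefit`, `p_success`, `cost`, `ce_score`, ordered by rank.
#' @export
score_pool <- function(countries, summaries, alpha, benefit_field,
                       p_source = c("constant_one", "column"),
                       c_source = c("constant_one", "column")) {
  stopifnot(inherits(countries, "country_table"))
  p_source <- match.arg(p_source)
  c_source <- match.arg(c_source)
  if (!benefit_field %in% names(countries)) {
    stop_validation("benefit field '%s' not found in country table", benefit_field)
  }
  idx <- match(summaries$country_id, countries$country_id)
  if (anyNA(idx)) {
    stop_validation("country table has no rows for: %s",
                    paste(summaries$country_id[is.na(idx)], collapse = ", "))
  }
  b <- coerce_numeric(countries[[benefit_field]][idx], benefit_field, "country table")
  if (any(!is.finite(b) | b < 0)) {
    stop_validation("benefit field '%s' must be finite and >= 0", benefit_field)
  }
  p <- if (p_source == "column") countries$p_success[idx] else rep(1, length(idx))
  cc <- if (c_source == "column") countries$cost[idx] else rep(1, length(idx))
  d <- discount_factor(summaries$i_unabatable, alpha, summaries$country_id)
  eb <- b * summaries$i_abatable * d
  if (any(!is.finite(p) | p < 0 | p > 1)) stop_validation("p_success must be in [0,1]")
  if (any(!is.finite(cc) | cc <= 0)) stop_validation("cost must be > 0")
  scored <- data.frame(
    country_id = summaries$country_id,
    b = b,
    i_abatable = summaries$i_abatable,
    i_unabatable = summaries$i_unabatable,
    discount = d,
    expected_benefit = eb,
    p_success = p,
    cost = cc,
    ce_score = eb * p / cc,
    stringsAsFactors = FALSE)
  rank_pool(scored)
}

#' Rank a scored pool deterministically
#'
#' Descending cost-effectiveness score; ties broken by ascending country id
#' (a deterministic lexicographic rule, required for reproducibility). Ranks
#' run 1..n with no gaps; tied candidates receive distinct consecutive ranks
#' in tie-break order.
#'
#' @param scored Data frame with at least `country_id` and `ce_score`.
#' @return The same data frame ordered by rank, with a `rank` column first,
#'   classed `scored_pool`.
#' @export
rank_pool <- function(scored) {
  stopifnot(is.data.frame(scored), all(c("country_id", "ce_score") %in% names(scored)))
  if (nrow(scored) == 0L) {
    out <- cbind(data.frame(rank = integer(0)), scored)
  } else {
    ord <- order(-scored$ce_score, scored$country_id, method = "radix")
    out <- scored[ord, , drop = FALSE]
    out <- cbind(data.frame(rank = seq_len(nrow(out))), out)
  }
  rownames(out) <- NULL
  class(out) <- c("scored_pool", "data.frame")
  out
}
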