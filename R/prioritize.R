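#' Run the full prioritization study
#'
#' One call that executes the three-step framework over a scenario matrix:
#' enabling-condition screening, threat-adjusted cost-effectiveness scoring
#' (with alpha shared per scheme over the full pool), ranking, and Jaccard
#' comparison of the top-k solution sets. The defaults reproduce the
#' canonical 4 x 2 x 2 design: four debt-to-GDP filters (none, >= 40%,
#' >= 60%, >= 80%), two benefits (EEZ area, coral-reef area), two threat
#' classifications (shipping abatable or not) — 16 scenarios, top-10 sets.
#'
#' @param countries A [country_table].
#' @param layers A [threat_table].
#' @param schemes Named list of [classification_scheme] objects.
#' @param filters Named list of filters (see [build_matrix()]); default
#'   [default_debt_filters()].
#' @param benefits Character vector of benefit fields.
#' @param top_k Solution-set size (default 10).
#' @param alpha_scope `"pool"` (default): one alpha per scheme over the full
#'   candidate pool, shared across scenarios; `"scenario"`: recomputed over
#'   each scenario's own post-screening pool.
#' @param compare If `TRUE` (default), attach a [compare_topk()] report over
#'   the scenarios whose pools can fill a top-k set (skipped with a message
#'   when fewer than two can).
#' @return Object of class `priority_run`: list with `specs`, `alphas`,
#'   `results`, `report` (or `NULL`), `top_k`, `countries`.
#' @examples
#' d <- generate_dataset(generator_config(n_countries = 20, seed = 7))
#' run <- prioritize(d$countries, d$layers, d$schemes, top_k = 5)
#' run
#' @export
prioritize <- function(countries, layers, schemes,
                       filters = default_debt_filters(),
                       benefits = c("eez_area_km2", "coral_area_km2"),
                       top_k = 10, alpha_scope = c("pool", "scenario"),
                       compare = TRUE) {
  alpha_scope <- match.arg(alpha_scope)
  specs <- build_matrix(filters, benefits, names(schemes), top_k = top_k)
  alphas <- if (alpha_scope == "pool") pool_alphas(countries, layers, schemes) else NULL
  results <- run_all(specs, countries, layers, schemes, alphas)
  report <- NULL
  if (isTRUE(compare)) {
    n_ok <- sum(vapply(results, `[[`, 0L, "pool_size") >= top_k)
    if (n_ok >= 2L) {
      report <- compare_topk(results, k = top_k)
    } else {
      message("prioritize: fewer than 2 scenarios can fill a top-", top_k,
              " set; comparison skipped")
    }
  }
  structure(list(specs = specs, alphas = alphas, results = results,
                 report = report, top_k = as.integer(top_k),
                 countries = countries),
            class = "priority_run")
}

#' @export
print.priority_run <- function(x, ...) {
  cat(sprintf("Debt-conversion prioritization: %d candidates, %d scenarios, top-%d sets\n",
              nrow(x$countries), length(x$results), x$top_k))
  if (!is.null(x$alphas)) {
    for (nm in names(x$alphas)) {
      cat(sprintf("  alpha[%s] = %.4f (1/max unabatable burden over full pool)\n",
                  nm, x$alphas[[nm]]$value))
    }
  } else {
    cat("  alpha recomputed per scenario pool\n")
  }
  r1 <- x$results[[1L]]
  cat(sprintf("  first scenario (%s) top ranks: %s\n", r1$scenario_id,
              paste(utils::head(r1$top_k_set, 5L), collapse = ", ")))
  if (!is.null(x$report)) {
    cat(sprintf("  Jaccard overlap of solution sets: min %.2f, mean %.2f, max %.2f\n",
                x$report$jaccard_min, x$report$jaccard_mean, x$report$jaccard_max))
  }
  invisible(x)
}

#' @export
summary.priority_run <- function(object, ...) {
  pools <- vapply(object$results, `[[`, 0L, "pool_size")
  ids <- vapply(object$results, `[[`, "", "scenario_id")
  cat("Scenario pools:\n")
  for (i in seq_along(ids)) {
    cat(sprintf("  %-45s pool %3d  alpha %.4f\n", ids[i], pools[i],
                object$results[[i]]$alpha_used))
  }
  if (!is.null(object$report)) print(object$report)
  invisible(object)
}

#' Plot original versus threat-adjusted benefit for one scenario
#'
#' Side-by-side bars of the raw benefit `b` and the expected benefit
#' `b * i_a * (1 - alpha * i_u)` for the top-ranked countries of one
#' scenario — the comparison that shows how threat accounting reshuffles
#' priorities away from the countries with the largest raw benefit. Because
#' the question of whether the pre-threat benefit should be read as `b` or
#' `b * i_a` is open, `original` selects either.
#'
#' @param x A `priority_run`.
#' @param scenario Scenario id or index (default 1).
#' @param n Number of top countries to show (default 10).
#' @param original `"b"` (raw benefit) or `"b_ia"` (benefit times abatable
#'   burden) as the pre-threat bar.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix of plotted values.
#' @export
plot.priority_run <- function(x, scenario = 1L, n = 10L,
                              original = c("b", "b_ia"), ...) {
  original <- match.arg(original)
  res <- if (is.character(scenario)) {
    ids <- vapply(x$results, `[[`, "", "scenario_id")
    x$results[[match(scenario, ids)]]
  } else x$results[[scenario]]
  if (is.null(res)) stop("unknown scenario: ", scenario)
  df <- utils::head(res$scored, n)
  orig <- if (original == "b") df$b else df$b * df$i_abatable
  m <- rbind(original = orig, expected = df$expected_benefit)
  colnames(m) <- df$country_id
  graphics::barplot(m, beside = TRUE, las = 2,
                    col = c("grey70", "grey30"),
                    ylab = sprintf("benefit (%s, km2)", res$benefit_field),
                    main = res$scenario_id, ...)
  graphics::legend("topright", fill = c("grey70", "grey30"),
                   legend = c(if (original == "b") "original (B)" else "original (B x Ia)",
                              "expected (threat-adjusted)"), bty = "n")
  invisible(m)
}
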