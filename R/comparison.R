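#' Jaccard similarity of two sets
#'
#' `|a intersect b| / |a union b|`, the overlap measure used to compare
#' top-k solution sets between scenarios. Comparing two empty sets is an
#' error (by convention, not 1): empty priority sets signal a misconfigured
#' run, and the quotient is undefined.
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return A scalar in \[0, 1\].
#' @examples
#' jaccard_index(c("A", "B", "C"), c("B", "C", "D"))  # 0.5
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    stop_validation("jaccard_index: both sets are empty; similarity is undefined")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Compare top-k solution sets across scenarios
#'
#' Scenarios whose post-screening pool is smaller than `k` cannot fill a
#' top-k set and are excluded (listed with the reason), generalizing the
#' removal of high-threshold scenarios with too few candidates. The report
#' holds the pairwise Jaccard matrix over the remaining scenarios, summary
#' statistics over the off-diagonal pairs, and per-country membership
#' counts/fractions over the compared sets.
#'
#' @param results List of `scenario_result` objects (see [run_scenario()]).
#' @param k Solution-set size (default 10). The top-k sets are re-derived
#'   from each scenario's ranking, so `k` may differ from the `top_k` the
#'   scenarios were run with, as long as pools are large enough.
#' @return An object of class `comparison_report`.
#' @export
compare_topk <- function(results, k = 10) {
  if (!is_count(k)) stop_validation("compare_topk: k must be a positive integer")
  ids <- vapply(results, `[[`, "", "scenario_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop_validation("compare_topk: duplicate scenario id(s): %s", paste(dup, collapse = ", "))
  }
  pool_sizes <- vapply(results, function(r) as.integer(r$pool_size), integer(1L))
  keep <- pool_sizes >= k
  excluded <- data.frame(scenario_id = ids[!keep],
                         reason = rep("pool_size<k", sum(!keep)),
                         pool_size = pool_sizes[!keep],
                         stringsAsFactors = FALSE)
  if (sum(keep) < 2L) {
    stop_validation("compare_topk: fewer than 2 scenarios with pool_size >= k = %d (excluded: %s)",
                    k, if (nrow(excluded)) paste(excluded$scenario_id, collapse = ", ") else "none")
  }
  kept <- results[keep]
  kept_ids <- ids[keep]
  sets <- lapply(kept, function(r) r$scored$country_id[seq_len(k)])
  n <- length(sets)
  jac <- matrix(1, n, n, dimnames = list(kept_ids, kept_ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      jac[i, j] <- jac[j, i] <- jaccard_index(sets[[i]], sets[[j]])
    }
  }
  off <- jac[upper.tri(jac)]
  union_set <- sort(unique(unlist(sets)))
  counts <- vapply(union_set, function(cid) {
    sum(vapply(sets, function(s) cid %in% s, logical(1L)))
  }, integer(1L))
  membership <- data.frame(country_id = union_set, count = counts,
                           fraction = counts / n, stringsAsFactors = FALSE)
  membership <- membership[order(-membership$count,
                                 xtfrm(membership$country_id)), , drop = FALSE]
  rownames(membership) <- NULL
  structure(list(compared_scenarios = kept_ids, excluded_scenarios = excluded,
                 k = as.integer(k), jaccard = jac,
                 jaccard_min = min(off), jaccard_max = max(off),
                 jaccard_mean = mean(off),
                 union_set = union_set, membership = membership),
            class = "comparison_report")
}

#' Membership summary of a comparison report
#'
#' Tabulates, for each country in the union of compared top-k sets, how many
#' solution sets contain it, and summarizes the distribution of those counts
#' (how many countries appear in exactly one set, two sets, ...). The
#' rendered percentages round half away from zero to whole percent; raw
#' fractions are preserved.
#'
#' @param report A [compare_topk()] result.
#' @return List with `table` (country, count, fraction; sorted by count
#'   descending then country id) and `distribution` (data frame: `count`,
#'   `n_countries`, `fraction`, `percentage` with whole-percent rounding).
#' @export
membership_summary <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  tab <- report$membership
  counts <- sort(unique(tab$count))
  n_union <- nrow(tab)
  dist <- data.frame(
    count = counts,
    n_countries = vapply(counts, function(k) sum(tab$count == k), integer(1L)))
  dist$fraction <- dist$n_countries / n_union
  dist$percentage <- round_half_away(100 * dist$fraction)
  list(table = tab, distribution = dist)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Top-%d comparison over %d scenarios (%d excluded: pool < k)\n",
              x$k, length(x$compared_scenarios), nrow(x$excluded_scenarios)))
  cat(sprintf("  Jaccard min/mean/max: %.2f / %.2f / %.2f\n",
              x$jaccard_min, x$jaccard_mean, x$jaccard_max))
  ms <- membership_summary(x)
  cat(sprintf("  %d countries in the union of solution sets\n", nrow(ms$table)))
  for (i in seq_len(nrow(ms$distribution))) {
    cat(sprintf("    in %d set(s): %d countries (%d%%)\n",
                ms$distribution$count[i], ms$distribution$n_countries[i],
                ms$distribution$percentage[i]))
  }
  invisible(x)
}
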