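#' Summarize per-country threat burdens under a classification scheme
#'
#' Threats are assumed additive: the abatable burden `i_abatable` is the sum
#' of the country's mean layer values over the scheme's abatable layers, and
#' `i_unabatable` the sum over unabatable layers. Because every layer falls
#' in exactly one class, `i_abatable + i_unabatable` is the total threat load
#' and is identical across all schemes partitioning the same layer set.
#' Summing (rather than averaging) lets the unabatable burden exceed 1,
#' which is why the discount needs the alpha scaling parameter
#' (see [compute_alpha()]).
#'
#' @param layers A [threat_table].
#' @param scheme A [classification_scheme] covering every layer in `layers`.
#' @param country_ids Countries to summarize (default: all in `layers`).
#' @return A data frame with columns `country_id`, `scheme_id`,
#'   `i_abatable`, `i_unabatable`, one row per requested country.
#' @export
summarize_threats <- function(layers, scheme, country_ids = NULL) {
  stopifnot(inherits(layers, "threat_table"), inherits(scheme, "classification_scheme"))
  uncovered <- setdiff(layers$layer_names, names(scheme$assignment))
  if (length(uncovered) > 0L) {
    stop_validation("scheme '%s' does not cover layer(s): %s",
                    scheme$scheme_id, paste(uncovered, collapse = ", "))
  }
  if (is.null(country_ids)) country_ids <- layers$country_ids
  missing_c <- setdiff(country_ids, layers$country_ids)
  if (length(missing_c) > 0L) {
    stop_validation("threat table has no rows for: %s", paste(missing_c, collapse = ", "))
  }
  m <- layers$values[country_ids, , drop = FALSE]
  cls <- scheme$assignment[layers$layer_names]
  ia <- rowSums(m[, cls == "abatable", drop = FALSE])
  iu <- rowSums(m[, cls == "unabatable", drop = FALSE])
  data.frame(country_id = country_ids, scheme_id = scheme$scheme_id,
             i_abatable = unname(ia), i_unabatable = unname(iu),
             stringsAsFactors = FALSE)
}

#' Derive the alpha scaling parameter for the unabatable-threat discount
#'
#' The expected benefit is discounted by `(1 - alpha * i_unabatable)`; alpha
#' must keep that factor non-negative over the whole candidate pool. Under
#' the default `pool_max_reciprocal` policy, `alpha = 1 / max(i_unabatable)`
#' over the supplied pool, which pins the discount to exactly 0 for the most
#' threatened country and keeps it in \[0, 1\] for everyone else. If every
#' country has zero unabatable burden, alpha is 0 by convention and the
#' discount degenerates to 1. A `fixed` alpha is accepted only if it keeps
#' the discount non-negative over the pool.
#'
#' @param summaries Data frame from [summarize_threats()] for the candidate
#'   pool the alpha should guard.
#' @param policy `"pool_max_reciprocal"` (default) or `"fixed"`.
#' @param fixed_value Non-negative scalar, required when `policy = "fixed"`.
#' @param pool_id Identifier recorded on the result (provenance only).
#' @return An object of class `alpha_parameter`: list with `value`,
#'   `policy`, `pool_id`, `max_iu`.
#' @examples
#' s <- data.frame(country_id = c("A", "B"), scheme_id = "s",
#'                 i_abatable = c(1, 2), i_unabatable = c(2, 4))
#' compute_alpha(s)$value  # 0.25
#' @export
compute_alpha <- function(summaries, policy = c("pool_max_reciprocal", "fixed"),
                          fixed_value = NULL, pool_id = "pool") {
  policy <- match.arg(policy)
  if (!is.data.frame(summaries) || nrow(summaries) == 0L) {
    stop_validation("compute_alpha: empty candidate pool")
  }
  iu <- summaries$i_unabatable
  if (any(!is.finite(iu) | iu < 0)) stop_validation("compute_alpha: i_unabatable must be finite and >= 0")
  max_iu <- max(iu)
  if (policy == "pool_max_reciprocal") {
    value <- if (max_iu > 0) 1 / max_iu else 0
  } else {
    if (is.null(fixed_value) || !is.numeric(fixed_value) || length(fixed_value) != 1L ||
        !is.finite(fixed_value) || fixed_value < 0) {
      stop_validation("compute_alpha: fixed policy needs a finite fixed_value >= 0")
    }
    neg <- which(1 - fixed_value * iu < -1e-12)
    if (length(neg) > 0L) {
      stop_validation("compute_alpha: fixed alpha %g gives a negative discount for country %s (i_unabatable = %g)",
                      fixed_value, summaries$country_id[neg[1L]], iu[neg[1L]])
    }
    value <- fixed_value
  }
  structure(list(value = value, policy = policy, pool_id = pool_id, max_iu = max_iu),
            class = "alpha_parameter")
}

#' @export
print.alpha_parameter <- function(x, ...) {
  cat(sprintf("alpha = %.6g (policy %s, pool '%s', max unabatable burden %.6g)\n",
              x$value, x$policy, x$pool_id, x$max_iu))
  invisible(x)
}

# Discount factor (1 - alpha * i_u). Residues within 1e-12 of zero are
# snapped to exactly 0 (max_iu * (1/max_iu) can miss 1 by one ulp); anything
# further below zero means alpha was not derived from a pool containing this
# country and is a hard error, never clamped.
discount_factor <- function(i_u, alpha, country_id = NULL) {
  stopifnot(inherits(alpha, "alpha_parameter"))
  d <- 1 - alpha$value * i_u
  d[abs(d) <= 1e-12] <- 0
  neg <- which(d < 0)
  if (length(neg) > 0L) {
    who <- if (!is.null(country_id)) country_id[neg[1L]] else sprintf("element %d", neg[1L])
    stop(sprintf("negative unabatable-threat discount (%g) for %s: alpha %g was not derived from a pool containing this burden (i_unabatable = %g)",
                 d[neg[1L]], who, alpha$value, i_u[neg[1L]]))
  }
  d
}
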