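test_that("the scenario matrix is the Cartesian product with distinct ids", {
  specs <- build_matrix(default_debt_filters(),
                        c("eez_area_km2", "coral_area_km2"), c("A", "B"))
  expect_length(specs, 16L)
  expect_length(build_matrix(list(all = NULL), "eez_area_km2", "A"), 1L)
  s12 <- build_matrix(list(all = NULL, ge60 = filter_rule("debt_to_gdp", "ge", 0.6)),
                      c("eez_area_km2", "coral_area_km2", "mangrove_km2"),
                      c("A", "B"))
  expect_length(s12, 12L)
  ids <- vapply(s12, `[[`, "", "scenario_id")
  expect_length(unique(ids), 12L)
  # deterministic nesting: filters outermost, schemes innermost
  expect_identical(ids[1:2], c("all|eez_area_km2|A", "all|eez_area_km2|B"))
  expect_error(build_matrix(list(a = NULL, a = NULL), "x", "A"), "duplicate")
  expect_error(build_matrix(list(), "x", "A"), "non-empty")
})

test_that("identical threat profiles rank purely by benefit", {
  ids <- sprintf("S%02d", 1:6)
  ct <- suppressMessages(country_table(data.frame(
    country_id = ids, debt_to_gdp = 0.7,
    eez_area_km2 = c(30, 10, 60, 20, 50, 40), coral_area_km2 = 1)))
  m <- matrix(0.4, 6, 4, dimnames = list(ids, c("f1", "f2", "c1", "c2")))
  layers <- threat_table(m)
  schemes <- list(A = classification_scheme(
    "A", c(f1 = "abatable", f2 = "abatable", c1 = "unabatable", c2 = "unabatable")))
  spec <- scenario_spec(NULL, "eez_area_km2", "A", top_k = 6)
  # under a shared alpha below 1/max the common discount is positive and
  # cancels, so only the benefit orders the pool
  s <- summarize_threats(layers, schemes$A)
  alphas <- list(A = compute_alpha(s, "fixed", fixed_value = 0.5))
  res <- run_scenario(spec, ct, layers, schemes, alphas)
  expect_identical(res$scored$country_id, ids[order(-ct$eez_area_km2)])
  # top_k = pool size covers the whole pool
  expect_setequal(res$top_k_set, ids)
  # at the pool-max-reciprocal alpha an all-equal pool sits exactly at the
  # zero-discount boundary: every score is 0 and the tie-break orders it
  res0 <- run_scenario(spec, ct, layers, schemes, pool_alphas(ct, layers, schemes))
  expect_true(all(res0$scored$ce_score == 0))
  expect_identical(res0$scored$country_id, sort(ids))
})

test_that("run_scenario equals hand-composed screening + summaries + scoring", {
  ct <- toy_countries(); layers <- toy_layers(); schemes <- toy_schemes()
  alphas <- pool_alphas(ct, layers, schemes)
  rule <- filter_rule("debt_to_gdp", "ge", 0.6)
  spec <- scenario_spec(rule, "coral_area_km2", "B", top_k = 2)
  res <- run_scenario(spec, ct, layers, schemes, alphas)

  pool <- apply_rule(ct, rule)$passed
  s <- summarize_threats(layers, schemes$B, pool)
  a <- alphas$B
  eb <- ct$coral_area_km2[match(pool, ct$country_id)] * s$i_abatable *
    (1 - a$value * s$i_unabatable)
  ord <- order(-eb, pool, method = "radix")
  expect_identical(res$scored$country_id, pool[ord])
  expect_equal(res$scored$ce_score, eb[ord], tolerance = 1e-12)
  expect_identical(res$top_k_set, pool[ord][1:2])
  expect_identical(res$pool_size, length(pool))
  expect_identical(res$alpha_used, a$value)
})

test_that("an empty post-screening pool warns and returns an empty ranking", {
  ct <- toy_countries(); layers <- toy_layers(); schemes <- toy_schemes()
  spec <- scenario_spec(filter_rule("debt_to_gdp", "ge", 5), "eez_area_km2", "A")
  expect_warning(res <- run_scenario(spec, ct, layers, schemes,
                                     pool_alphas(ct, layers, schemes)),
                 "no candidates")
  expect_identical(res$pool_size, 0L)
  expect_length(res$top_k_set, 0L)
})

test_that("scenarios are independent and share per-scheme burdens under pooled alpha", {
  ct <- toy_countries(); layers <- toy_layers(); schemes <- toy_schemes()
  alphas <- pool_alphas(ct, layers, schemes)
  specs <- build_matrix(default_debt_filters()[c("all", "ge60")],
                        c("eez_area_km2", "coral_area_km2"), c("A", "B"),
                        top_k = 3)
  res <- run_all(specs, ct, layers, schemes, alphas)
  perm <- rev(seq_along(specs))
  res_perm <- run_all(specs[perm], ct, layers, schemes, alphas)
  for (i in seq_along(specs)) {
    expect_identical(res_perm[[which(perm == i)]]$scored, res[[i]]$scored)
  }
  # a country in two pools keeps identical burdens and discount per scheme
  ids <- vapply(res, `[[`, "", "scenario_id")
  a_all <- res[[match("all|eez_area_km2|A", ids)]]$scored
  a_60 <- res[[match("ge60|eez_area_km2|A", ids)]]$scored
  shared <- intersect(a_all$country_id, a_60$country_id)
  for (col in c("i_abatable", "i_unabatable", "discount")) {
    expect_identical(a_all[[col]][match(shared, a_all$country_id)],
                     a_60[[col]][match(shared, a_60$country_id)], label = col)
  }
  # a failing scenario aborts with its id attached
  bad <- scenario_spec(NULL, "not_a_field", "A")
  expect_error(run_all(list(bad), ct, layers, schemes, alphas),
               "all\\|not_a_field\\|A")
})

test_that("per-scenario alpha recomputation pins the pool maximum discount to zero", {
  ct <- toy_countries(); layers <- toy_layers(); schemes <- toy_schemes()
  spec <- scenario_spec(filter_rule("debt_to_gdp", "ge", 0.6), "eez_area_km2", "A")
  res <- run_scenario(spec, ct, layers, schemes, alphas = NULL)
  expect_equal(min(res$scored$discount), 0)
  s <- summarize_threats(layers, schemes$A, res$scored$country_id)
  expect_equal(res$alpha_used, 1 / max(s$i_unabatable))
})
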