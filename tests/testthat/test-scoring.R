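test_that("expected benefit follows b * i_a * (1 - alpha*i_u)", {
  a <- fixed_alpha(0.18)
  expect_equal(expected_benefit(100, 0.5, 3.0, a), 23.0)        # 100*0.5*0.46
  expect_equal(expected_benefit(100, 0.5, 0, a), 50)            # no unabatable discount
  # at the pool maximum the discount is exactly zero, whatever b and i_a
  pool <- compute_alpha(data.frame(country_id = "M", scheme_id = "s",
                                   i_abatable = 1, i_unabatable = 7))
  expect_identical(expected_benefit(1e9, 123, 7, pool), 0)
  # exceeding the guarded pool is a hard error, never a clamp
  expect_error(expected_benefit(10, 1, 8, pool), "negative")
  expect_error(expected_benefit(-1, 1, 1, a), "'b'")
})

test_that("ce_score scales with p and 1/cost", {
  a <- fixed_alpha(0.1)
  eb <- expected_benefit(200, 0.4, 2, a)
  expect_equal(ce_score(200, 0.4, 2, a, p_success = 1, cost = 1), eb)
  expect_equal(ce_score(200, 0.4, 2, a, cost = 2), eb / 2)
  expect_equal(ce_score(200, 0.4, 2, a, p_success = 0), 0)
  expect_error(ce_score(200, 0.4, 2, a, cost = 0), "cost")
  expect_error(ce_score(200, 0.4, 2, a, p_success = 2), "p_success")
})

test_that("ranking is by descending score with lexicographic tie-break", {
  df <- data.frame(country_id = c("A", "B", "C"), ce_score = c(5, 9, 5))
  r <- rank_pool(df)
  expect_identical(r$country_id, c("B", "A", "C"))
  expect_identical(r$rank, 1:3)
  one <- rank_pool(data.frame(country_id = "Z", ce_score = 0))
  expect_identical(one$rank, 1L)
  empty <- rank_pool(data.frame(country_id = character(0), ce_score = numeric(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("score_pool agrees with element-wise recomputation on random pools", {
  withr::local_seed(31)
  for (i in 1:15) {
    ct <- random_countries(12)
    layers <- random_layers(ct$country_id, p = 5)
    sc <- random_scheme(layers)
    s <- summarize_threats(layers, sc)
    a <- compute_alpha(s)
    scored <- score_pool(ct, s, a, "eez_area_km2",
                         p_source = "column", c_source = "column")
    # independent recomputation straight from the formula
    idx <- match(scored$country_id, ct$country_id)
    sidx <- match(scored$country_id, s$country_id)
    manual <- ct$eez_area_km2[idx] * s$i_abatable[sidx] *
      (1 - a$value * s$i_unabatable[sidx]) * ct$p_success[idx] / ct$cost[idx]
    manual[abs(1 - a$value * s$i_unabatable[sidx]) <= 1e-12] <- 0
    expect_equal(scored$ce_score, manual, tolerance = 1e-12)
    expect_identical(order(-scored$ce_score, scored$country_id, method = "radix"),
                     seq_len(nrow(scored)))
  }
})

test_that("the score is strictly monotone in each argument where defined", {
  a <- fixed_alpha(0.15)
  base <- ce_score(100, 0.5, 2, a, p_success = 0.8, cost = 2)
  expect_gt(ce_score(101, 0.5, 2, a, 0.8, 2), base)     # b up
  expect_gt(ce_score(100, 0.6, 2, a, 0.8, 2), base)     # i_a up
  expect_gt(ce_score(100, 0.5, 2, a, 0.9, 2), base)     # p up
  expect_lt(ce_score(100, 0.5, 2, a, 0.8, 3), base)     # cost up
  expect_lt(ce_score(100, 0.5, 2.5, a, 0.8, 2), base)   # i_u up (alpha > 0)
  # with alpha = 0 the unabatable burden has no effect
  a0 <- fixed_alpha(0)
  expect_equal(ce_score(100, 0.5, 9, a0), ce_score(100, 0.5, 0, a0))
})

test_that("rescaling every benefit by a common factor leaves the ranking unchanged", {
  withr::local_seed(32)
  ct <- random_countries(15)
  layers <- random_layers(ct$country_id)
  sc <- random_scheme(layers)
  s <- summarize_threats(layers, sc)
  a <- compute_alpha(s)
  r1 <- score_pool(ct, s, a, "eez_area_km2")
  ct2 <- ct
  ct2$eez_area_km2 <- ct2$eez_area_km2 * 1e-3
  r2 <- score_pool(ct2, s, a, "eez_area_km2")
  expect_identical(r1$country_id, r2$country_id)
  expect_equal(r2$ce_score, r1$ce_score * 1e-3, tolerance = 1e-12)
})

test_that("threat accounting can demote the largest-benefit country", {
  # the country with the biggest EEZ carries little abatable threat and a
  # heavy unabatable burden, so a smaller, heavily-fished country overtakes it
  ct <- suppressMessages(country_table(data.frame(
    country_id = c("BIG", "MID"), debt_to_gdp = c(0.7, 0.7),
    eez_area_km2 = c(1.3e6, 9e5), coral_area_km2 = c(1, 1))))
  s <- data.frame(country_id = c("BIG", "MID"), scheme_id = "s",
                  i_abatable = c(0.4, 2.0), i_unabatable = c(4.0, 2.5))
  a <- compute_alpha(s)
  scored <- score_pool(ct, s, a, "eez_area_km2")
  expect_identical(which.max(ct$eez_area_km2), 1L)
  expect_identical(scored$country_id[1L], "MID")
})
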