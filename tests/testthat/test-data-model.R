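test_that("country loader fills defaults and validates the core fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_id,debt_to_gdp,eez_area_km2,coral_area_km2",
               "AAA,0.5,100,10", "BBB,0.7,200,0", "CCC,0.9,300,5"), path)
  expect_message(ct <- load_country_table(path), "p_success")
  expect_s3_class(ct, "country_table")
  expect_equal(nrow(ct), 3L)
  expect_equal(ct$p_success, rep(1, 3))
  expect_equal(ct$cost, rep(1, 3))
  expect_equal(ct$debt_to_gdp, c(0.5, 0.7, 0.9))

  # percent flag stores the ratio
  writeLines(c("country_id,debt_to_gdp,eez_area_km2,coral_area_km2,p_success,cost",
               "AAA,60,100,10,1,1"), path)
  expect_equal(load_country_table(path, percent = TRUE)$debt_to_gdp, 0.6)
})

test_that("country validation rejects duplicates, negatives and junk numerics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_id,debt_to_gdp,eez_area_km2,coral_area_km2,p_success,cost",
               "SYC,0.6,100,10,1,1", "SYC,0.7,200,0,1,1"), path)
  expect_error(load_country_table(path), "SYC")

  writeLines(c("country_id,debt_to_gdp,eez_area_km2,coral_area_km2,p_success,cost",
               "AAA,0.6,-5,10,1,1"), path)
  expect_error(load_country_table(path), "eez_area_km2")

  writeLines(c("country_id,debt_to_gdp,eez_area_km2,coral_area_km2,p_success,cost",
               "AAA,oops,100,10,1,1"), path)
  expect_error(load_country_table(path), "unparseable")

  df <- data.frame(country_id = "A", debt_to_gdp = 0.5, eez_area_km2 = 1,
                   coral_area_km2 = 1, p_success = 1.2, cost = 1)
  expect_error(country_table(df), "p_success")
  df$p_success <- 1; df$cost <- 0
  expect_error(country_table(df), "cost")
})

test_that("country table write/read round-trips at full precision", {
  ct <- random_countries(12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_country_table(ct, path)
  back <- suppressMessages(load_country_table(path))
  for (col in c("debt_to_gdp", "eez_area_km2", "coral_area_km2", "p_success", "cost")) {
    expect_identical(back[[col]], ct[[col]], label = col)
  }
})

test_that("wide and long threat layouts load to identical tables", {
  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_id,f1,f2,c1",
               "AAA,0.5,0.5,0.5", "BBB,0.5,0.5,0.5"), wide)
  tw <- load_threat_layers(wide, "wide")
  expect_equal(dim(tw$values), c(2L, 3L))
  expect_true(all(tw$values == 0.5))

  long <- withr::local_tempfile(fileext = ".csv")
  rows <- c("country_id,layer_name,value")
  for (cid in c("AAA", "BBB")) for (l in c("f1", "f2", "c1")) {
    rows <- c(rows, sprintf("%s,%s,0.5", cid, l))
  }
  writeLines(rows, long)
  tl <- load_threat_layers(long, "long")
  expect_identical(tl$values, tw$values)
  expect_identical(tl$layer_names, tw$layer_names)
})

test_that("threat loader rejects out-of-range and missing cells with coordinates", {
  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_id,f1,c1", "AAA,1.2,0.3"), wide)
  expect_error(load_threat_layers(wide), "AAA.*f1|f1.*AAA")

  long <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_id,layer_name,value",
               "AAA,f1,0.2", "AAA,c1,0.3", "BBB,f1,0.4"), long)
  expect_error(load_threat_layers(long, "long"), "missing cell")

  writeLines(c("country_id,f1,c1", "AAA,0.2,", "BBB,0.4,0.5"), wide)
  expect_error(load_threat_layers(wide), "missing cell")
})

test_that("classification schemes validate labels, coverage and the shipping variant", {
  sc <- classification_scheme("s", c(f1 = "abatable", c1 = "unabatable"))
  expect_s3_class(sc, "classification_scheme")
  expect_error(classification_scheme("s", c(f1 = "abatable", c1 = "maybe")),
               "maybe")
  expect_error(classification_scheme("s", c(f1 = "abatable", f2 = "abatable")),
               "at least one")

  schemes <- toy_schemes()
  diff <- names(which(schemes$A$assignment != schemes$B$assignment))
  expect_identical(diff, "shipping")

  # a layer present in the table but absent from the scheme is a coverage error
  layers <- toy_layers()
  partial <- classification_scheme("p", c(trawling = "abatable", artisanal = "abatable",
                                          heat_stress = "unabatable",
                                          acidification = "unabatable"))
  expect_error(summarize_threats(layers, partial), "shipping")
})

test_that("scheme JSON round-trips through the loader", {
  path <- withr::local_tempfile(fileext = ".json")
  write_classification(toy_schemes()$B, path)
  back <- load_classification(path)
  expect_identical(back$scheme_id, "B")
  expect_identical(back$assignment, toy_schemes()$B$assignment)
})

test_that("random corrupt tables are rejected by validation", {
  withr::local_seed(404)
  for (i in 1:20) {
    ct <- as.data.frame(random_countries(6))
    bad <- sample(c("dup", "neg_area", "neg_debt", "bad_p", "bad_cost"), 1L)
    switch(bad,
      dup = { ct$country_id[2L] <- ct$country_id[1L] },
      neg_area = { ct$eez_area_km2[3L] <- -1 },
      neg_debt = { ct$debt_to_gdp[4L] <- -0.2 },
      bad_p = { ct$p_success[1L] <- 1.5 },
      bad_cost = { ct$cost[5L] <- 0 })
    expect_error(country_table(ct), class = "debtprior_validation_error",
                 label = bad)
    m <- matrix(runif(12), 4, 3,
                dimnames = list(sprintf("X%d", 1:4), sprintf("l%d", 1:3)))
    m[sample.int(12, 1L)] <- sample(c(-0.1, 1.1, NA, Inf), 1L)
    expect_error(threat_table(m), class = "debtprior_validation_error")
  }
})

test_that("write_results writes one CSV per scenario plus report and manifest, deterministically", {
  d <- toy_countries(); layers <- toy_layers(); schemes <- toy_schemes()
  specs <- build_matrix(list(all = NULL), c("eez_area_km2", "coral_area_km2"),
                        c("A", "B"), top_k = 3)
  alphas <- pool_alphas(d, layers, schemes)
  results <- run_all(specs, d, layers, schemes, alphas)
  report <- compare_topk(results, k = 3)

  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  man <- write_results(results, report, out1, config = list(x = 1), seed = 9)
  expect_setequal(list.files(out1),
                  c(paste0("scenario_", gsub("[^A-Za-z0-9._-]", "_",
                                             vapply(results, `[[`, "", "scenario_id")), ".csv"),
                    "report.json", "manifest.json"))
  write_results(results, report, out2, config = list(x = 1), seed = 9)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)),
                     label = f)
  }
  csv <- utils::read.csv(file.path(out1, list.files(out1, pattern = "csv$")[1L]))
  expect_identical(names(csv),
                   c("rank", "country_id", "b", "i_abatable", "i_unabatable",
                     "discount", "expected_benefit", "p_success", "cost", "ce_score"))

  out3 <- withr::local_tempdir()
  expect_warning(write_results(list(), NULL, out3), "empty")
  expect_identical(list.files(out3), "manifest.json")
})
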