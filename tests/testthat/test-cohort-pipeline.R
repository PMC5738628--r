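test_that("missing required columns raise a schema error naming the column", {
  raw <- planted_claims()
  raw$enrollment_months_before <- NULL
  err <- expect_error(apply_inclusion(raw), class = "preopbayes_schema_error")
  expect_match(conditionMessage(err), "enrollment_months_before")
})

test_that("inclusion rules cut exactly at their stated boundaries", {
  raw <- planted_claims()
  kept <- apply_inclusion(raw)
  # age 19 out, 20 in, 64 in, 65 out; enrollment 11 out, 12 in;
  # inpatient+emergency out; missing age out; inpatient alone stays
  expect_setequal(kept$patient_id,
                  c("p02", "p03", "p06", "p09", "p10"))
  flow <- inclusion_flow(kept)
  expect_equal(flow$n[flow$rule == "assessed"], 10)
  expect_equal(flow$n[flow$rule == "included"], 5)
  expect_equal(sum(flow$n[c(2, 3, 4, 5)]), -5)
})

test_that("the filter agrees with a brute-force row scan and is idempotent", {
  cfg <- small_config(seed = 57L)
  raw <- generate_cohort(cfg)
  kept <- apply_inclusion(raw)
  expect_equal(nrow(kept), sum(oracle_included(raw)))
  expect_setequal(kept$patient_id, raw$patient_id[oracle_included(raw)])
  twice <- apply_inclusion(kept)
  strip <- function(x) { attr(x, "exclusions") <- NULL; as.data.frame(x) }
  expect_equal(strip(twice), strip(kept))
  expect_true(all(inclusion_flow(twice)$n[2:5] == 0))
})

test_that("outcome window is closed at both ends", {
  d <- as.Date("2015-01-01")
  raw <- tibble::tibble(
    surgery_date = rep(d, 4),
    cbc_date = c(d - 60, d - 61, d, as.Date(NA)),
    metabolic_date = rep(as.Date(NA), 4),
    coagulation_date = rep(as.Date(NA), 4),
    lft_date = rep(as.Date(NA), 4)
  )
  out <- derive_outcome(raw)$outcome
  expect_identical(out, c(TRUE, FALSE, TRUE, FALSE))
  # a post-surgery order never counts
  raw$cbc_date <- d + 1
  expect_false(any(derive_outcome(raw)$outcome))
})

test_that("outcome derivation matches the per-row date-arithmetic oracle", {
  cfg <- small_config(seed = 63L)
  raw <- generate_cohort(cfg)
  expect_identical(derive_outcome(raw)$outcome, oracle_outcome(raw))
  # widening the window is monotone: no true ever becomes false
  o30 <- derive_outcome(raw, 30)$outcome
  o90 <- derive_outcome(raw, 90)$outcome
  expect_true(all(o90[o30]))
})

test_that("tabulation matches a brute-force group-by and conserves rows", {
  cfg <- small_config(seed = 71L)
  cohort <- code_covariates(derive_outcome(apply_inclusion(generate_cohort(cfg))))
  tab <- tabulate_beds(cohort)
  brute <- table(cohort$institution_beds >= 100, cohort$outcome)
  expect_equal(tab$z[tab$group == "small"], unname(brute["FALSE", "TRUE"]))
  expect_equal(tab$z[tab$group == "large"], unname(brute["TRUE", "TRUE"]))
  expect_equal(sum(tab$n), nrow(cohort))
  # all-positive toy cohort: z = n in each stratum
  toy <- tibble::tibble(outcome = rep(TRUE, 5),
                        beds_ge_100 = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  ttab <- tabulate_beds(toy)
  expect_equal(ttab$z, ttab$n)
  expect_error(tabulate_beds(toy[0, ]), class = "preopbayes_empty_input_error")
})

test_that("overall and group rates are exact ratios", {
  tab <- bundled_counts()
  expect_equal(overall_rate(tab), 40822 / 69252)
  rates <- group_rates(tab)
  expect_equal(rates$rate, c(18993 / 41157, 21829 / 28095))
  zero <- two_by_two(0, 5, 0, 3)
  expect_equal(overall_rate(zero), 0)
  expect_error(overall_rate(two_by_two(0, 0, 0, 0)),
               class = "preopbayes_empty_input_error")
})

test_that("two_by_two validates its counts", {
  expect_error(two_by_two(5, 3, 1, 2), class = "preopbayes_config_error")
  expect_error(two_by_two(-1, 3, 1, 2), class = "preopbayes_config_error")
  expect_error(two_by_two(1.5, 3, 1, 2), class = "preopbayes_config_error")
})

test_that("covariate coding assigns ages and operation-count quartiles", {
  cohort <- tibble::tibble(
    age = c(22, 30, 40, 50, 60, 33),
    institution_id = c("a", "a", "a", "b", "c", "d"),
    institution_beds = c(150L, 150L, 150L, 50L, 99L, 100L),
    outcome = rep(TRUE, 6)
  )
  coded <- code_covariates(cohort)
  expect_equal(as.character(coded$age_category),
               c("<25", "25-34", "35-44", "45-54", "55-64", "25-34"))
  expect_identical(coded$beds_ge_100, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  # institution counts: a=3, b=1, c=1, d=1 -> a in the top quartile, rest Q1
  expect_equal(max(coded$n_operations_quartile[coded$institution_id == "a"]), 4)
  expect_true(all(coded$n_operations_quartile[coded$institution_id != "a"] == 1))
})

test_that("the packaged fixture matches the in-code counts and writes JSON", {
  tab <- example_bedsize_counts()
  expect_equal(as.data.frame(tab), as.data.frame(bundled_counts()))
  path <- withr::local_tempfile(fileext = ".json")
  write_two_by_two(tab, path)
  payload <- jsonlite::read_json(path)
  expect_equal(payload$counts$z_small, 18993)
  expect_equal(payload$overall_rate, 40822 / 69252)
})
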