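test_that("invalid configurations are rejected with the offending field named", {
  expect_error(small_config(prop_large = 1.5), "prop_large",
               class = "preopbayes_config_error")
  expect_error(small_config(sigma0_sq = -0.1), "sigma0_sq",
               class = "preopbayes_config_error")
  expect_error(small_config(n_patients = 10, n_institutions = 40),
               "n_institutions", class = "preopbayes_config_error")
  expect_error(
    small_config(true_beta = c(female = 0.1)), "true_beta",
    class = "preopbayes_config_error"
  )
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- small_config()
  expect_identical(generate_institutions(cfg), generate_institutions(cfg))
  r1 <- generate_cohort(cfg)
  r2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # a different seed changes the draw
  r3 <- generate_cohort(small_config(seed = 102L))
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("random intercepts have the configured variance", {
  # degenerate variance: intercepts exactly zero
  inst0 <- generate_institutions(small_config(sigma0_sq = 0))
  expect_true(all(inst0$random_intercept == 0))
  # law of large numbers at 5000 institutions, unit variance
  inst1 <- generate_institutions(
    small_config(n_patients = 5000, n_institutions = 5000, sigma0_sq = 1)
  )
  expect_lt(abs(var(inst1$random_intercept) - 1), 0.05)
})

test_that("institution table respects the bed-size split", {
  cfg <- small_config(n_patients = 4000, n_institutions = 2000,
                      prop_large = 0.406)
  inst <- generate_institutions(cfg)
  expect_true(all(inst$beds[inst$beds_ge_100] >= 100))
  expect_true(all(inst$beds[!inst$beds_ge_100] < 100))
  # share of large institutions within 3 binomial SE of the configured value
  se <- sqrt(0.406 * 0.594 / nrow(inst))
  expect_lt(abs(mean(inst$beds_ge_100) - 0.406), 3 * se)
  expect_equal(sum(inst$weight), 1)
})

test_that("patient covariate marginals are faithful on the raw table", {
  cfg <- small_config(n_patients = 20000, n_institutions = 500, seed = 7L)
  raw <- generate_cohort(cfg)
  for (nm in names(cfg$covariate_marginals)) {
    p <- cfg$covariate_marginals[[nm]]
    se <- sqrt(p * (1 - p) / nrow(raw))
    expect_lt(abs(mean(raw[[nm]]) - p), 3 * se)
  }
  expect_equal(mean(raw$inpatient), 1 - mean(raw$outpatient))
})

test_that("null model gives a 50% outcome rate", {
  cfg <- small_config(
    n_patients = 20000, n_institutions = 100, sigma0_sq = 0,
    true_intercept = 0,
    covariate_marginals = c(female = 0.5),
    true_beta = c(female = 0, beds_ge_100 = 0, teaching = 0),
    seed = 13L
  )
  raw <- generate_cohort(cfg)
  rate <- mean(cohort_truth(raw)$latent_outcome)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / nrow(raw)))
})

test_that("default configuration hits the published 59% testing prevalence", {
  # full stated scale: 69,252 surgeries over 9,922 institutions; the error
  # budget combines binomial noise with the cluster-level noise induced by
  # Dirichlet-weighted random intercepts (dominant term, ~0.004 here)
  cfg <- synthetic_config(seed = 20260917L)
  raw <- generate_cohort(cfg)
  truth <- cohort_truth(raw)
  prev <- mean(truth$latent_outcome)
  w <- truth$institutions$weight
  cluster_se <- sqrt(sum(w^2) * cfg$sigma0_sq) * 0.25
  binom_se <- sqrt(0.59 * 0.41 / cfg$n_patients)
  expect_lt(abs(prev - 0.59), 4 * sqrt(cluster_se^2 + binom_se^2))
})

test_that("derived outcome equals the latent ordering event", {
  cfg <- small_config(seed = 23L)
  raw <- generate_cohort(cfg)
  derived <- derive_outcome(raw, window_days = cfg$test_window_days)
  expect_identical(derived$outcome, cohort_truth(raw)$latent_outcome)
})

test_that("crude bed-size odds ratio converges to the generating effect", {
  cfg <- small_config(
    n_patients = 60000, n_institutions = 600, sigma0_sq = 0,
    target_prevalence = 0.5,
    covariate_marginals = c(female = 0.5),
    true_beta = c(female = 0, beds_ge_100 = log(2.64), teaching = 0),
    p_age_out = 0, p_short_enrollment = 0, p_emergency_inpatient = 0,
    seed = 31L
  )
  raw <- generate_cohort(cfg)
  cohort <- code_covariates(derive_outcome(raw))
  tab <- tabulate_beds(cohort)
  or <- (tab$z[tab$group == "large"] * (tab$n[tab$group == "small"] - tab$z[tab$group == "small"])) /
    ((tab$n[tab$group == "large"] - tab$z[tab$group == "large"]) * tab$z[tab$group == "small"])
  expect_lt(abs(or - 2.64), 0.15)
})

test_that("between-institution outcome heterogeneity grows with sigma0_sq", {
  logit_var <- function(sig2) {
    cfg <- small_config(n_patients = 30000, n_institutions = 100,
                        sigma0_sq = sig2, seed = 41L)
    raw <- generate_cohort(cfg)
    lat <- cohort_truth(raw)$latent_outcome
    by_inst <- tapply(lat, raw$institution_id, function(y) {
      # continuity-corrected empirical log-odds
      qlogis((sum(y) + 0.5) / (length(y) + 1))
    })
    sizes <- tapply(lat, raw$institution_id, length)
    var(by_inst[sizes >= 30])
  }
  v <- vapply(c(0, 0.5, 2), logit_var, numeric(1))
  expect_true(v[1] < v[2] && v[2] < v[3])
})

test_that("cohort and truth round-trip through disk as CSV + JSON", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n_patients = 200, n_institutions = 10)
  raw <- generate_cohort(cfg)
  paths <- write_cohort(raw, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[["claims"]], show_col_types = FALSE)
  expect_equal(nrow(back), 200)
  expect_s3_class(back$surgery_date, "Date")
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$sigma0_sq, cfg$sigma0_sq)
  expect_equal(truth$beta$beds_ge_100, log(2.64))
})
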