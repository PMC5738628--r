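# shared fixtures, all built in code

# the published bed-size counts (identical to the packaged CSV)
bundled_counts <- function() {
  two_by_two(z_small = 18993, n_small = 41157,
             z_large = 21829, n_large = 28095)
}

# a small, fast generator configuration; individual tests override fields
small_config <- function(...) {
  defaults <- list(
    n_patients = 4000, n_institutions = 40, sigma0_sq = 0.25,
    covariate_marginals = c(female = 0.57, outpatient = 0.69),
    true_beta = c(female = log(1.2), outpatient = log(0.5),
                  beds_ge_100 = log(2.64), teaching = log(0.71)),
    p_age_out = 0.05, p_short_enrollment = 0.05, p_emergency_inpatient = 0.05,
    seed = 101L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# hand-written raw claims rows with known planted rule violations
planted_claims <- function() {
  d <- as.Date("2014-06-01")
  tibble::tibble(
    patient_id = sprintf("p%02d", 1:10),
    age = c(19, 20, 64, 65, 40, 40, 40, NA, 40, 40),
    institution_id = rep(c("a", "b"), 5),
    institution_beds = rep(c(50L, 200L), 5),
    surgery_date = rep(d, 10),
    enrollment_months_before = c(24, 24, 24, 24, 11, 12, 24, 24, 24, 24),
    inpatient = c(rep(FALSE, 6), TRUE, FALSE, TRUE, FALSE),
    emergency_additional = c(rep(FALSE, 6), TRUE, FALSE, FALSE, FALSE),
    cbc_date = c(d - 10, d - 61, d - 60, d, NA, d - 30, d - 5, d - 5, NA, NA),
    metabolic_date = rep(as.Date(NA), 10),
    coagulation_date = c(rep(as.Date(NA), 9), d - 400),
    lft_date = rep(as.Date(NA), 10)
  )
}

# independent brute-force row scan used as the filter oracle
oracle_included <- function(raw) {
  keep <- logical(nrow(raw))
  req <- c("patient_id", "age", "institution_id", "surgery_date",
           "enrollment_months_before", "inpatient", "emergency_additional")
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    complete <- !anyNA(row[req])
    keep[i] <- complete && row$age >= 20 && row$age <= 64 &&
      row$enrollment_months_before >= 12 &&
      !(isTRUE(row$inpatient) && isTRUE(row$emergency_additional))
  }
  keep
}

# independent per-row date-arithmetic oracle for the outcome
oracle_outcome <- function(raw, window = 60) {
  vapply(seq_len(nrow(raw)), function(i) {
    hit <- FALSE
    for (col in c("cbc_date", "metabolic_date", "coagulation_date", "lft_date")) {
      if (!col %in% names(raw)) next
      dte <- raw[[col]][i]
      if (!is.na(dte)) {
        lag <- as.numeric(raw$surgery_date[i] - dte)
        if (lag >= 0 && lag <= window) hit <- TRUE
      }
    }
    hit
  }, logical(1))
}

# minimal fitted object with a degenerate chain, for summary-shape tests
constant_fit <- function(value = log(2), n = 500) {
  structure(
    list(
      chains = list(list(
        beta = matrix(value, n, 1, dimnames = list(NULL, "x")),
        sigma0_sq = NULL, c = NULL,
        acceptance = c(x = 0)
      )),
      spec = glmm_spec("x"),
      settings = list(n_iter = n, burn_in = 0, thin = 1, chains = 1,
                      seed = 1, random_intercept = FALSE),
      data_info = list(n_obs = 1, n_rows = 1, n_institutions = 0L),
      institution_levels = NULL
    ),
    class = "preop_glmm"
  )
}
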