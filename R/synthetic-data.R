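#' Configuration for the synthetic claims-cohort generator
#'
#' Describes a synthetic population of low-risk surgeries clustered within
#' institutions, with binary patient covariates drawn independently at stated
#' marginal frequencies, institution-level covariates (bed-size class, teaching
#' status), institution random intercepts on the log-odds scale, and a binary
#' testing outcome generated from a logistic model. Defaults emulate a
#' nationwide Japanese employment-based claims cohort: 69,252 surgeries across
#' 9,922 institutions, 57.0% female, 31.0% inpatient, 40.6% of surgeries at
#' institutions with >=100 beds, and an overall testing prevalence of 59.0%.
#' Default effect sizes are the log odds ratios of the published multivariable
#' analysis of that cohort.
#'
#' @param n_patients Number of surgeries (rows). Default 69252.
#' @param n_institutions Number of institutions. Default 9922.
#' @param prop_large Probability an institution has >=100 beds. Because
#'   institution weights are drawn independently of bed class, this is also the
#'   expected per-surgery share of the large-bed class. Default 0.406.
#' @param institution_size_dispersion Concentration of the symmetric Dirichlet
#'   from which surgeries-per-institution weights are drawn; smaller values
#'   give a heavier right skew. Default 0.3.
#' @param covariate_marginals Named vector of Bernoulli marginals for the
#'   patient-level binary covariates.
#' @param institution_marginals Named vector of Bernoulli marginals for
#'   institution-level binary covariates other than bed class. Default
#'   `c(teaching = 0.078)`.
#' @param true_beta Named vector of log-odds effects; must cover every patient
#'   and institution covariate plus `beds_ge_100`.
#' @param true_intercept Intercept on the log-odds scale, or `NULL` (default)
#'   to calibrate it deterministically so the marginal outcome prevalence
#'   equals `target_prevalence` (see [calibrate_intercept()]).
#' @param target_prevalence Marginal outcome prevalence used when
#'   `true_intercept` is `NULL`. Default 0.59.
#' @param sigma0_sq Variance of the institution random intercepts. Default 0.5.
#' @param test_window_days Preoperative window length in days. Default 60.
#' @param test_inclusion_probs Named vector: probability each test type (cbc,
#'   metabolic, coagulation, lft) receives an in-window order date when the
#'   latent ordering event occurs. At least one type is always ordered.
#' @param p_negative_old_test Probability, per test type, that an
#'   outcome-negative surgery carries an out-of-window (historical) order date.
#'   Default 0.3.
#' @param p_age_out,p_short_enrollment,p_emergency_inpatient Probabilities of
#'   planting rows violating each inclusion rule (age outside 20--64,
#'   enrollment under 12 months, inpatient with additional/emergency
#'   procedure), so the inclusion filter has work to do. Defaults 0.08, 0.07,
#'   0.07 (about a fifth of rows excluded overall).
#' @param study_start,study_end Calendar bounds of the uniform surgery dates.
#'   Defaults 2012-04-01 and 2016-03-31.
#' @param seed Integer RNG seed; identical configurations produce bit-identical
#'   tables.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_patients = 69252,
    n_institutions = 9922,
    prop_large = 0.406,
    institution_size_dispersion = 0.3,
    covariate_marginals = c(
      female = 0.570, antiplatelet = 0.025, anticoagulant = 0.005,
      acei_arb = 0.078, diuretics = 0.016, chemotherapy = 0.011,
      outpatient = 0.690, ophthalmologic = 0.40
    ),
    institution_marginals = c(teaching = 0.078),
    true_beta = c(
      female = log(1.03), antiplatelet = log(1.40), anticoagulant = log(3.57),
      acei_arb = log(1.53), diuretics = log(1.40), chemotherapy = log(1.55),
      outpatient = log(0.37), ophthalmologic = log(1.58),
      beds_ge_100 = log(2.64), teaching = log(0.71)
    ),
    true_intercept = NULL,
    target_prevalence = 0.59,
    sigma0_sq = 0.5,
    test_window_days = 60,
    test_inclusion_probs = c(cbc = 0.980, metabolic = 0.841,
                             coagulation = 0.603, lft = 0.814),
    p_negative_old_test = 0.3,
    p_age_out = 0.08,
    p_short_enrollment = 0.07,
    p_emergency_inpatient = 0.07,
    study_start = as.Date("2012-04-01"),
    study_end = as.Date("2016-03-31"),
    seed = 1L) {
  cfg <- list(
    n_patients = n_patients, n_institutions = n_institutions,
    prop_large = prop_large,
    institution_size_dispersion = institution_size_dispersion,
    covariate_marginals = covariate_marginals,
    institution_marginals = institution_marginals,
    true_beta = true_beta, true_intercept = true_intercept,
    target_prevalence = target_prevalence, sigma0_sq = sigma0_sq,
    test_window_days = test_window_days,
    test_inclusion_probs = test_inclusion_probs,
    p_negative_old_test = p_negative_old_test,
    p_age_out = p_age_out, p_short_enrollment = p_short_enrollment,
    p_emergency_inpatient = p_emergency_inpatient,
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  count_fields <- c("n_patients", "n_institutions", "test_window_days")
  for (f in count_fields)
    if (length(cfg[[f]]) != 1L || !is.numeric(cfg[[f]]) || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]]))
      abort_config(f, "must be a single positive integer")
  if (cfg$n_institutions > cfg$n_patients)
    abort_config("n_institutions", "must not exceed n_patients")
  prob_fields <- c("prop_large", "target_prevalence", "p_negative_old_test",
                   "p_age_out", "p_short_enrollment", "p_emergency_inpatient")
  for (f in prob_fields)
    if (length(cfg[[f]]) != 1L || !is.numeric(cfg[[f]]) ||
        cfg[[f]] < 0 || cfg[[f]] > 1)
      abort_config(f, "must be a probability in [0, 1]")
  for (f in c("covariate_marginals", "institution_marginals",
              "test_inclusion_probs")) {
    v <- cfg[[f]]
    if (length(v) > 0 && (is.null(names(v)) || any(!nzchar(names(v)))))
      abort_config(f, "must be a named numeric vector")
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      abort_config(f, "entries must be probabilities in [0, 1]")
  }
  if (length(cfg$sigma0_sq) != 1L || !is.finite(cfg$sigma0_sq) || cfg$sigma0_sq < 0)
    abort_config("sigma0_sq", "must be a single non-negative number")
  if (length(cfg$institution_size_dispersion) != 1L ||
      !is.finite(cfg$institution_size_dispersion) ||
      cfg$institution_size_dispersion <= 0)
    abort_config("institution_size_dispersion", "must be a single positive number")
  needed <- c(names(cfg$covariate_marginals), "beds_ge_100",
              names(cfg$institution_marginals))
  absent <- setdiff(needed, names(cfg$true_beta))
  if (length(absent) > 0)
    abort_config("true_beta",
                 sprintf("is missing effects for: %s", paste(absent, collapse = ", ")))
  if (!is.null(cfg$true_intercept) &&
      (length(cfg$true_intercept) != 1L || !is.finite(cfg$true_intercept)))
    abort_config("true_intercept", "must be NULL or a single finite number")
  if (cfg$study_end < cfg$study_start)
    abort_config("study_end", "must not precede study_start")
  structure(cfg, class = "synthetic_config")
}

#' Calibrate the generator intercept to a target prevalence
#'
#' Solves for the intercept `b0` such that the marginal outcome probability
#' `E[plogis(b0 + X'beta + c)]` equals the configured target, where the
#' expectation enumerates all covariate patterns exactly (covariates are
#' independent Bernoulli) and integrates the normal random intercept on a fixed
#' quadrature grid. Deterministic: no random draws are used.
#'
#' @param config A [synthetic_config()].
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  marg <- c(config$covariate_marginals,
            beds_ge_100 = unname(config$prop_large),
            config$institution_marginals)
  beta <- config$true_beta[names(marg)]
  k <- length(marg)
  patterns <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(patterns) <- names(marg)
  w <- exp(patterns %*% log(marg) + (1 - patterns) %*% log1p(-marg))
  s <- drop(patterns %*% beta)
  if (config$sigma0_sq > 0) {
    sd0 <- sqrt(config$sigma0_sq)
    cgrid <- seq(-6 * sd0, 6 * sd0, length.out = 201)
    cw <- dnorm(cgrid, 0, sd0)
    cw <- cw / sum(cw)
  } else {
    cgrid <- 0
    cw <- 1
  }
  prevalence <- function(b0) {
    p <- plogis(outer(s, cgrid, `+`) + b0)
    sum(w * drop(p %*% cw))
  }
  uniroot(function(b0) prevalence(b0) - config$target_prevalence,
          interval = c(-20, 20), tol = 1e-8)$root
}

# institution table; assumes the RNG state has been set by the caller
generate_institutions_impl <- function(config) {
  n <- config$n_institutions
  is_large <- runif(n) < config$prop_large
  beds <- integer(n)
  # log-uniform bed counts within each class; only the <100/>=100 split matters
  beds[is_large] <- round(10^runif(sum(is_large), log10(100), log10(1000)))
  beds[!is_large] <- round(10^runif(sum(!is_large), log10(10), log10(99)))
  beds <- pmax(pmin(beds, 1000L), 10L)
  beds[is_large] <- pmax(beds[is_large], 100L)
  beds[!is_large] <- pmin(beds[!is_large], 99L)
  inst <- tibble(
    institution_id = sprintf("inst%05d", seq_len(n)),
    beds = as.integer(beds),
    beds_ge_100 = is_large
  )
  for (nm in names(config$institution_marginals))
    inst[[nm]] <- runif(n) < config$institution_marginals[[nm]]
  inst$random_intercept <- rnorm(n, 0, sqrt(config$sigma0_sq))
  # symmetric Dirichlet weights -> heavy right skew of surgeries/institution
  g <- stats::rgamma(n, shape = config$institution_size_dispersion, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)
  inst$weight <- g / sum(g)
  inst
}

#' Generate the synthetic institution table
#'
#' Draws institutions with a bed count (log-uniform within the <100 and >=100
#' classes), institution-level covariates, i.i.d. normal random intercepts with
#' variance `sigma0_sq`, and Dirichlet surgery-allocation weights.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `institution_id`, `beds`, `beds_ge_100`,
#'   institution covariates, `random_intercept`, `weight`.
#' @export
generate_institutions <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  generate_institutions_impl(config)
}

#' Generate a synthetic raw claims table
#'
#' Produces one row per surgery: patient covariates drawn independently at the
#' configured marginals, an institution assignment (multinomial over Dirichlet
#' weights), a uniform surgery date within the study window, planted
#' inclusion-rule violations, and per-test order dates. A latent test-ordering
#' event occurs with probability `plogis(b0 + X'beta + c_institution)`; when it
#' occurs at least one of the four test types receives an order date within the
#' preoperative window, and when it does not any generated test dates fall
#' strictly outside the window. The generating truth (intercept, effects,
#' random-intercept variance, institution table) is attached as attribute
#' `"truth"` for parameter-recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return A raw claims tibble; see [apply_inclusion()] and [derive_outcome()]
#'   for the downstream schema.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  inst <- generate_institutions_impl(config)
  n <- config$n_patients

  counts <- drop(rmultinom(1, n, prob = inst$weight))
  idx <- rep(seq_len(nrow(inst)), counts)

  raw <- tibble(
    patient_id = sprintf("pat%06d", seq_len(n)),
    institution_id = inst$institution_id[idx],
    institution_beds = inst$beds[idx]
  )

  # age: mostly uniform on the eligible 20-64 range, with planted violations
  age <- sample(20:64, n, replace = TRUE)
  out_of_range <- runif(n) < config$p_age_out
  age[out_of_range] <- sample(c(15:19, 65:75), sum(out_of_range), replace = TRUE)
  raw$age <- age

  enr <- sample(12:120, n, replace = TRUE)
  short <- runif(n) < config$p_short_enrollment
  enr[short] <- sample(0:11, sum(short), replace = TRUE)
  raw$enrollment_months_before <- enr

  for (nm in names(config$covariate_marginals))
    raw[[nm]] <- runif(n) < config$covariate_marginals[[nm]]
  # the surgical setting enters the model as `outpatient`; when the config
  # omits it, draw the setting flag at the default inpatient share instead
  raw$inpatient <- if ("outpatient" %in% names(raw)) !raw$outpatient
                   else runif(n) < 0.31
  raw$emergency_additional <- raw$inpatient &
    (runif(n) < ifelse(config$p_emergency_inpatient > 0,
                       config$p_emergency_inpatient / max(mean(raw$inpatient), 1e-9),
                       0))

  span <- as.integer(config$study_end - config$study_start)
  raw$surgery_date <- config$study_start + sample(0:span, n, replace = TRUE)

  b0 <- config$true_intercept %||% calibrate_intercept(config)
  X <- cbind(
    as.matrix(raw[names(config$covariate_marginals)]) * 1,
    beds_ge_100 = as.numeric(inst$beds_ge_100[idx])
  )
  for (nm in names(config$institution_marginals))
    X <- cbind(X, setNames(list(as.numeric(inst[[nm]][idx])), nm)[[1]])
  colnames(X) <- c(names(config$covariate_marginals), "beds_ge_100",
                   names(config$institution_marginals))
  eta <- b0 + drop(X %*% config$true_beta[colnames(X)]) +
    inst$random_intercept[idx]
  ordered_tests <- runif(n) < plogis(eta)

  w <- config$test_window_days
  for (nm in names(config$test_inclusion_probs)) {
    col <- paste0(nm, "_date")
    has <- ifelse(ordered_tests,
                  runif(n) < config$test_inclusion_probs[[nm]],
                  runif(n) < config$p_negative_old_test)
    lag <- ifelse(ordered_tests,
                  sample(0:w, n, replace = TRUE),
                  w + sample(1:300, n, replace = TRUE))
    raw[[col]] <- dplyr::if_else(has, raw$surgery_date - lag, as.Date(NA))
  }
  # guarantee at least one in-window order for every latent positive
  none <- ordered_tests &
    rowSums(!is.na(as.data.frame(raw[paste0(names(config$test_inclusion_probs),
                                            "_date")]))) == 0
  if (any(none))
    raw$cbc_date[none] <- raw$surgery_date[none] -
      sample(0:w, sum(none), replace = TRUE)

  attr(raw, "truth") <- list(
    intercept = b0,
    beta = config$true_beta,
    sigma0_sq = config$sigma0_sq,
    latent_outcome = ordered_tests,
    institutions = inst
  )
  raw
}

#' Retrieve the generating truth of a synthetic cohort
#'
#' @param raw A table from [generate_cohort()].
#' @return A list with `intercept`, `beta`, `sigma0_sq`, `latent_outcome` and
#'   the institution table.
#' @export
cohort_truth <- function(raw) {
  truth <- attr(raw, "truth")
  if (is.null(truth))
    rlang::abort("table carries no generating truth; was it produced by generate_cohort()?")
  truth
}

#' Write a synthetic cohort and its generating truth to disk
#'
#' Writes the claims table as CSV (ISO-8601 dates) and the generating truth
#' (intercept, effects, random-intercept variance) as JSON.
#'
#' @param raw A table from [generate_cohort()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(raw, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  claims_path <- file.path(dir, "claims.csv")
  truth_path <- file.path(dir, "truth.json")
  readr::write_csv(raw, claims_path)
  truth <- cohort_truth(raw)
  jsonlite::write_json(
    list(intercept = truth$intercept, beta = as.list(truth$beta),
         sigma0_sq = truth$sigma0_sq),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(claims = claims_path, truth = truth_path))
}
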