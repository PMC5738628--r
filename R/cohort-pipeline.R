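#' Two-by-two counts of testing outcome by institution bed-size group
#'
#' Container for the aggregated counts feeding the conjugate beta-binomial
#' comparison: the number of outcome-positive surgeries (`z`) and total
#' surgeries (`n`) at institutions with fewer than 100 beds (`small`) and at
#' institutions with 100 beds or more (`large`). Group labels are explicit
#' because subscript conventions for the two groups are notoriously easy to
#' flip.
#'
#' @param z_small,n_small Outcome-positive count and total for the <100-bed
#'   group.
#' @param z_large,n_large Outcome-positive count and total for the >=100-bed
#'   group.
#' @return A tibble of class `two_by_two` with columns `group`, `z`, `n`.
#' @examples
#' two_by_two(z_small = 18993, n_small = 41157, z_large = 21829, n_large = 28095)
#' @export
two_by_two <- function(z_small, n_small, z_large, n_large) {
  vals <- c(z_small = z_small, n_small = n_small,
            z_large = z_large, n_large = n_large)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v < 0 || v != round(v))
      abort_config(nm, "must be a single non-negative integer count")
  }
  if (z_small > n_small) abort_config("z_small", "exceeds n_small")
  if (z_large > n_large) abort_config("z_large", "exceeds n_large")
  out <- tibble(
    group = c("small", "large"),
    z = c(z_small, z_large),
    n = c(n_small, n_large)
  )
  class(out) <- c("two_by_two", class(out))
  out
}

#' @export
print.two_by_two <- function(x, ...) {
  cat("2x2 outcome counts by institution bed size\n")
  lab <- c(small = "<100 beds", large = ">=100 beds")
  for (i in seq_len(nrow(x))) {
    r <- x$z[i] / x$n[i]
    cat(sprintf("  %-10s z = %6.0f / n = %6.0f  (%.1f%%)\n",
                lab[[x$group[i]]], x$z[i], x$n[i], 100 * r))
  }
  invisible(x)
}

#' Bundled example counts from a nationwide claims cohort
#'
#' Published aggregate counts of preoperative blood testing by institution
#' bed-size group, from a retrospective cohort of 69,252 low-risk surgeries in
#' a Japanese employment-based claims database (2012--2016): 18,993/41,157
#' tested surgeries at institutions with <100 beds and 21,829/28,095 at
#' institutions with >=100 beds.
#'
#' @return A [two_by_two()] object.
#' @examples
#' example_bedsize_counts()
#' @export
example_bedsize_counts <- function() {
  path <- system.file("extdata", "bedsize_testing_counts.csv",
                      package = "preopbayes", mustWork = TRUE)
  counts <- readr::read_csv(path, show_col_types = FALSE)
  two_by_two(
    z_small = counts$z[counts$group == "small"],
    n_small = counts$n[counts$group == "small"],
    z_large = counts$z[counts$group == "large"],
    n_large = counts$n[counts$group == "large"]
  )
}

required_claims_columns <- c(
  "patient_id", "age", "institution_id", "surgery_date",
  "enrollment_months_before", "inpatient", "emergency_additional"
)

check_claims_schema <- function(raw, required = required_claims_columns) {
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    rlang::abort(
      sprintf("claims table is missing required column(s): %s",
              paste(missing, collapse = ", ")),
      class = "preopbayes_schema_error", columns = missing
    )
  invisible(raw)
}

#' Apply cohort inclusion and exclusion rules
#'
#' Retains surgeries for patients aged 20--64 years with at least 12 months of
#' enrollment before the procedure, and drops inpatient procedures performed in
#' conjunction with additional/emergency procedures as well as rows with
#' missing required fields. Rules are applied sequentially so each excluded row
#' is attributed to the first rule it violates, mirroring a study flow diagram.
#'
#' @param raw A raw claims tibble (one row per surgery) with at least the
#'   columns `patient_id`, `age`, `institution_id`, `surgery_date`,
#'   `enrollment_months_before`, `inpatient`, `emergency_additional`.
#' @param min_age,max_age Inclusive age bounds in years. Defaults 20 and 64.
#' @param min_enrollment_months Minimum months of insurance enrollment before
#'   the index surgery. Default 12.
#' @return The included rows, with an `exclusions` attribute (a tibble of
#'   per-rule drop counts) retrievable with [inclusion_flow()]. Applying the
#'   filter twice is a no-op.
#' @export
apply_inclusion <- function(raw, min_age = 20, max_age = 64,
                            min_enrollment_months = 12) {
  check_claims_schema(raw)
  req <- required_claims_columns
  n0 <- nrow(raw)

  miss <- rowSums(is.na(raw[req])) > 0
  kept <- raw[!miss, , drop = FALSE]
  n_missing <- sum(miss)

  age_ok <- kept$age >= min_age & kept$age <= max_age
  n_age <- sum(!age_ok)
  kept <- kept[age_ok, , drop = FALSE]

  enr_ok <- kept$enrollment_months_before >= min_enrollment_months
  n_enr <- sum(!enr_ok)
  kept <- kept[enr_ok, , drop = FALSE]

  emerg <- kept$inpatient & kept$emergency_additional
  n_emerg <- sum(emerg)
  kept <- kept[!emerg, , drop = FALSE]

  flow <- tibble(
    rule = c("assessed", "missing required fields",
             sprintf("age outside [%d, %d]", min_age, max_age),
             sprintf("enrollment < %d months", min_enrollment_months),
             "inpatient with additional/emergency procedure", "included"),
    n = c(n0, -n_missing, -n_age, -n_enr, -n_emerg, nrow(kept))
  )
  attr(kept, "exclusions") <- flow
  kept
}

#' Retrieve the exclusion flow of a filtered cohort
#'
#' @param cohort A cohort returned by [apply_inclusion()].
#' @return A tibble with one row per exclusion rule and the (signed) number of
#'   rows involved, starting at the assessed total and ending at the included
#'   total.
#' @export
inclusion_flow <- function(cohort) {
  flow <- attr(cohort, "exclusions")
  if (is.null(flow))
    rlang::abort("cohort carries no exclusion ledger; was it produced by apply_inclusion()?")
  flow
}

test_date_columns <- c("cbc_date", "metabolic_date", "coagulation_date", "lft_date")

#' Derive the preoperative-testing outcome from test order dates
#'
#' The outcome is positive when any of the four blood-test types (complete
#' blood count, basic metabolic panel, coagulation tests, liver function
#' tests) was ordered within the preoperative window before the index surgery.
#' The window is closed on both ends: an order on the surgery day (lag 0) and
#' an order exactly `window_days` before both count. Absent dates never
#' contribute.
#'
#' @param raw A claims tibble with a `Date` column `surgery_date` and optional
#'   `Date` columns `cbc_date`, `metabolic_date`, `coagulation_date`,
#'   `lft_date`.
#' @param window_days Length of the preoperative window in days. Default 60.
#' @return `raw` with a logical `outcome` column appended.
#' @export
derive_outcome <- function(raw, window_days = 60) {
  if (!"surgery_date" %in% names(raw))
    rlang::abort("claims table is missing required column(s): surgery_date",
                 class = "preopbayes_schema_error", columns = "surgery_date")
  if (length(window_days) != 1L || !is.numeric(window_days) || window_days <= 0)
    abort_config("window_days", "must be a single positive number")
  present <- intersect(test_date_columns, names(raw))
  out <- rep(FALSE, nrow(raw))
  for (col in present) {
    lag <- as.numeric(raw$surgery_date - raw[[col]])
    hit <- !is.na(lag) & lag >= 0 & lag <= window_days
    out <- out | hit
  }
  raw$outcome <- out
  raw
}

#' Code analysis covariates against their reference levels
#'
#' Adds the derived covariates used by the mixed model: `beds_ge_100`
#' (institution has >=100 beds), `age_category` (bands `<25`, `25-34`, `35-44`,
#' `45-54`, `55-64`; reference `<25`), and `n_operations_quartile` (quartile of
#' the institution's surgery count within the cohort, nearest-rank, ties share
#' a quartile; reference Q1).
#'
#' @param cohort An included-cohort tibble with `age`, `institution_id` and
#'   `institution_beds` columns.
#' @return The cohort with the derived columns appended.
#' @export
code_covariates <- function(cohort) {
  if (!all(c("institution_id", "institution_beds", "age") %in% names(cohort)))
    rlang::abort("cohort must have institution_id, institution_beds and age columns",
                 class = "preopbayes_schema_error")
  cohort$beds_ge_100 <- cohort$institution_beds >= 100
  cohort$age_category <- cut(
    cohort$age, breaks = c(-Inf, 24, 34, 44, 54, Inf),
    labels = c("<25", "25-34", "35-44", "45-54", "55-64"), right = TRUE
  )
  inst_n <- table(cohort$institution_id)
  # nearest-rank quartile of institution-level surgery counts; every surgery
  # at an institution inherits its institution's quartile, ties share
  qs <- stats::quantile(as.numeric(inst_n), probs = c(0.25, 0.5, 0.75), type = 1)
  inst_q <- 1L + findInterval(as.numeric(inst_n), qs, left.open = TRUE)
  names(inst_q) <- names(inst_n)
  cohort$n_operations_quartile <- inst_q[as.character(cohort$institution_id)]
  cohort
}

#' Tabulate outcome counts by institution bed-size group
#'
#' @param cohort A cohort tibble with logical columns `outcome` and
#'   `beds_ge_100` (the latter added by [code_covariates()] or present
#'   directly).
#' @return A [two_by_two()] object.
#' @export
tabulate_beds <- function(cohort) {
  if (nrow(cohort) == 0L)
    rlang::abort("cannot tabulate an empty cohort",
                 class = "preopbayes_empty_input_error")
  if (!"beds_ge_100" %in% names(cohort)) {
    if (!"institution_beds" %in% names(cohort))
      rlang::abort("cohort must have a beds_ge_100 or institution_beds column",
                   class = "preopbayes_schema_error")
    cohort$beds_ge_100 <- cohort$institution_beds >= 100
  }
  if (!"outcome" %in% names(cohort))
    rlang::abort("cohort must have an outcome column (see derive_outcome())",
                 class = "preopbayes_schema_error")
  small <- cohort[!cohort$beds_ge_100, , drop = FALSE]
  large <- cohort[cohort$beds_ge_100, , drop = FALSE]
  two_by_two(
    z_small = sum(small$outcome), n_small = nrow(small),
    z_large = sum(large$outcome), n_large = nrow(large)
  )
}

#' Overall outcome rate of a two-by-two table
#'
#' Computed as an exact ratio of integer counts; rounding to display precision
#' is left to the caller.
#'
#' @param tab A [two_by_two()] object.
#' @return The pooled proportion `(z_small + z_large) / (n_small + n_large)`.
#' @export
overall_rate <- function(tab) {
  stopifnot(inherits(tab, "two_by_two"))
  total <- sum(tab$n)
  if (total == 0)
    rlang::abort("overall rate undefined: zero total count",
                 class = "preopbayes_empty_input_error")
  sum(tab$z) / total
}

#' Per-group outcome rates
#'
#' @param tab A [two_by_two()] object.
#' @return A tibble with columns `group`, `z`, `n`, `rate`.
#' @export
group_rates <- function(tab) {
  stopifnot(inherits(tab, "two_by_two"))
  dplyr::mutate(as_tibble(tab), rate = .data$z / .data$n)
}

#' Write a two-by-two table and its derived rates as JSON
#'
#' @param tab A [two_by_two()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_two_by_two <- function(tab, path) {
  stopifnot(inherits(tab, "two_by_two"))
  payload <- list(
    counts = as.list(setNames(tab$z, paste0("z_", tab$group))),
    totals = as.list(setNames(tab$n, paste0("n_", tab$group))),
    rates = as.list(setNames(tab$z / tab$n, paste0("rate_", tab$group))),
    overall_rate = overall_rate(tab)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
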