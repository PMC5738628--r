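# MCMC convergence diagnostics: autocorrelation, effective sample size,
# split scale reduction. Numbers, not pictures, so they can be asserted on.

#' Autocorrelation function of a chain
#'
#' Standard biased autocovariance estimator normalized by lag 0. A degenerate
#' (constant) chain has no defined autocorrelation; it is returned as `NA`
#' beyond lag 0 with a `"degenerate"` flag attribute rather than an error.
#'
#' @param chain Numeric vector of draws.
#' @param max_lag Largest lag, strictly less than the chain length. Default
#'   100.
#' @return A tibble with columns `lag` (0..max_lag) and `autocorrelation`.
#' @export
autocorrelation <- function(chain, max_lag = 100) {
  n <- length(chain)
  if (max_lag >= n)
    abort_config("max_lag", "must be smaller than the chain length")
  if (stats::var(chain) == 0 || !is.finite(stats::var(chain))) {
    out <- tibble(lag = 0:max_lag,
                  autocorrelation = c(1, rep(NA_real_, max_lag)))
    attr(out, "flag") <- "degenerate"
    return(out)
  }
  rho <- drop(acf(chain, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf)
  tibble(lag = 0:max_lag, autocorrelation = rho)
}

#' Effective sample size of a chain
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated at the
#' first non-positive lag (initial positive sequence). Invariant under affine
#' transformations of the chain. Degenerate chains return 0 with a warning.
#'
#' @param chain Numeric vector of draws.
#' @param max_lag Cap on the lags examined. Default `min(n - 1, 1000)`.
#' @return A single number in `(0, n]` (0 for a degenerate chain).
#' @export
effective_sample_size <- function(chain, max_lag = NULL) {
  n <- length(chain)
  max_lag <- max_lag %||% min(n - 1L, 1000L)
  ac <- autocorrelation(chain, max_lag)
  if (identical(attr(ac, "flag"), "degenerate")) {
    rlang::warn("degenerate (constant) chain: effective sample size is 0")
    return(0)
  }
  rho <- ac$autocorrelation[-1]
  cut <- which(rho <= 0)
  if (length(cut) > 0) rho <- rho[seq_len(cut[1] - 1L)]
  min(n, n / (1 + 2 * sum(rho)))
}

#' Split scale-reduction factor (R-hat)
#'
#' Classic (rank-free) potential scale reduction on split chains: each chain is
#' halved, and the square root of the ratio of the pooled-variance estimate to
#' the mean within-chain variance is returned. Values near 1 indicate the
#' chains agree in location and spread.
#'
#' @param chains A numeric vector (one chain, split in half), a list of numeric
#'   vectors, or a matrix with one chain per column. Chains of unequal length
#'   are trimmed to the shortest with a warning.
#' @return A single number, >= 1 up to sampling noise.
#' @export
split_rhat <- function(chains) {
  if (is.numeric(chains) && is.null(dim(chains))) chains <- list(chains)
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  lens <- lengths(chains)
  if (length(unique(lens)) > 1L) {
    rlang::warn("chains have unequal lengths; trimming to the shortest")
    chains <- lapply(chains, function(x) x[seq_len(min(lens))])
  }
  n2 <- 2L * (min(lens) %/% 2L)
  halves <- unlist(lapply(chains, function(x) {
    x <- x[seq_len(n2)]
    list(x[seq_len(n2 / 2)], x[(n2 / 2 + 1):n2])
  }), recursive = FALSE)
  m <- length(halves)
  n <- n2 / 2
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence report for a fitted model
#'
#' Per-parameter effective sample size, lag-1 autocorrelation, split R-hat
#' (across chains, or split halves of a single chain), acceptance rate, and
#' warning flags. Default thresholds flag `ess < 100` and `rhat > 1.05`.
#'
#' @param fit A `preop_glmm` fit.
#' @param max_lag Autocorrelation horizon. Default 100.
#' @param ess_warn,rhat_warn Flag thresholds. Defaults 100 and 1.05.
#' @return A tibble with one row per monitored parameter.
#' @export
diagnose <- function(fit, max_lag = 100, ess_warn = 100, rhat_warn = 1.05) {
  stopifnot(inherits(fit, "preop_glmm"))
  params <- colnames(fit$chains[[1]]$beta)
  if (fit$settings$random_intercept) params <- c(params, "sigma0_sq")
  acc <- rowMeans(vapply(fit$chains, `[[`, numeric(length(fit$chains[[1]]$acceptance)),
                         "acceptance"))
  purrr::map_dfr(params, function(pm) {
    per_chain <- lapply(fit$chains, function(ch)
      if (pm == "sigma0_sq") ch$sigma0_sq else ch$beta[, pm])
    pooled <- unlist(per_chain, use.names = FALSE)
    ml <- min(max_lag, length(per_chain[[1]]) - 1L)
    ess <- sum(vapply(per_chain, effective_sample_size, numeric(1)))
    rhat <- split_rhat(per_chain)
    lag1 <- autocorrelation(per_chain[[1]], ml)$autocorrelation[2]
    flags <- c(
      if (is.finite(ess) && ess < ess_warn) sprintf("low ESS (%.0f)", ess),
      if (is.finite(rhat) && rhat > rhat_warn) sprintf("high R-hat (%.3f)", rhat)
    )
    tibble(
      parameter = pm, mean = mean(pooled), sd = sd(pooled), ess = ess,
      rhat = rhat, lag1_acf = lag1,
      acceptance_rate = unname(acc[pm]),
      flags = paste(flags, collapse = "; ")
    )
  })
}
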