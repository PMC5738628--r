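#' Specification of the Bayesian logistic mixed model
#'
#' Two-level logistic regression for the testing outcome: fixed effects with
#' independent normal priors, an institution random intercept `c ~ N(0,
#' sigma0_sq)`, and a gamma hyperprior on the random-intercept variance. The
#' default fixed-effect prior is N(0, 1000) on the log-odds scale and the
#' default hyperprior is Gamma(shape = 0.001, rate = 0.001) (mean 1, variance
#' 1000), the conventional vague variance prior.
#'
#' @param predictors Character vector of predictor column names (binary or
#'   numeric), in the order they should be reported.
#' @param fixed_prior_mean Prior mean of every fixed effect. Default 0.
#' @param fixed_prior_variance Prior variance of every fixed effect. Default
#'   1000.
#' @param hyper_shape,hyper_rate Shape and rate of the gamma hyperprior on
#'   `sigma0_sq`. Defaults 0.001 and 0.001.
#' @return A validated list of class `glmm_spec`.
#' @export
glmm_spec <- function(predictors, fixed_prior_mean = 0,
                      fixed_prior_variance = 1000,
                      hyper_shape = 0.001, hyper_rate = 0.001) {
  if (!is.character(predictors) || length(predictors) < 1L)
    abort_config("predictors", "must be a non-empty character vector")
  if (length(fixed_prior_variance) != 1L || !is.finite(fixed_prior_variance) ||
      fixed_prior_variance <= 0)
    abort_config("fixed_prior_variance", "must be a single positive number")
  if (length(hyper_shape) != 1L || !is.finite(hyper_shape) || hyper_shape <= 0)
    abort_config("hyper_shape", "must be a single positive number")
  if (length(hyper_rate) != 1L || !is.finite(hyper_rate) || hyper_rate <= 0)
    abort_config("hyper_rate", "must be a single positive number")
  structure(
    list(predictors = predictors, fixed_prior_mean = fixed_prior_mean,
         fixed_prior_variance = fixed_prior_variance,
         hyper_shape = hyper_shape, hyper_rate = hyper_rate),
    class = "glmm_spec"
  )
}

#' Aggregate a row-wise cohort to binomial sufficient statistics
#'
#' Groups the cohort by institution and unique covariate pattern and counts
#' outcome-positive (`z`) and total (`n`) surgeries. The Bernoulli and
#' aggregated binomial log-likelihoods are identical, so fitting on the
#' aggregate is an exact speed-up.
#'
#' @param cohort A cohort tibble with an `outcome` column.
#' @param predictors Character vector of covariate columns to keep.
#' @param institution Name of the institution id column; use `NULL` for a
#'   model without random effects. Default `"institution_id"`.
#' @return A tibble with the institution column (if any), the predictors, `z`
#'   and `n`.
#' @export
aggregate_binomial <- function(cohort, predictors,
                               institution = "institution_id") {
  needed <- c(institution, predictors, "outcome")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0)
    rlang::abort(sprintf("cohort is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "preopbayes_schema_error", columns = missing)
  cohort |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(institution, predictors)))) |>
    dplyr::summarise(z = sum(.data$outcome), n = dplyr::n(), .groups = "drop")
}

# internal: design pieces for the sampler / log posterior
glmm_design <- function(agg, spec, random_intercept = TRUE) {
  X <- cbind(`(Intercept)` = rep(1, nrow(agg)),
             as.matrix(dplyr::select(agg, dplyr::all_of(spec$predictors))) * 1)
  inst <- if (random_intercept) {
    if (!"institution_id" %in% names(agg))
      rlang::abort("random-intercept model needs an institution_id column",
                   class = "preopbayes_schema_error")
    factor(agg$institution_id)
  } else NULL
  list(X = X, z = agg$z, n = agg$n, inst = inst,
       inst_idx = if (is.null(inst)) NULL else as.integer(inst),
       n_inst = if (is.null(inst)) 0L else nlevels(inst))
}

glmm_loglik <- function(eta, z, n) sum(z * eta - n * log1pexp(eta))

#' Log posterior of the logistic mixed model
#'
#' Sum of the binomial (Bernoulli) log-likelihood with logit link, normal
#' log-priors on the fixed effects, normal log-densities of the institution
#' intercepts given `sigma0_sq`, and the gamma log-hyperprior on `sigma0_sq`.
#' States with `sigma0_sq <= 0` return `-Inf` (a rejected region, not an
#' error). Accepts either a row-wise cohort (`outcome` column) or a
#' pre-aggregated binomial table (`z`, `n` columns); the two give identical
#' values.
#'
#' @param beta Named or positional numeric vector: intercept followed by the
#'   coefficients of `spec$predictors`.
#' @param data Cohort or aggregated binomial tibble.
#' @param spec A [glmm_spec()].
#' @param c_inst Numeric vector of institution intercepts (one per distinct
#'   institution, in factor-level order), or `NULL` for a fixed-effects-only
#'   model.
#' @param sigma0_sq Random-intercept variance (ignored when `c_inst` is
#'   `NULL`).
#' @return A single number (possibly `-Inf`).
#' @export
log_posterior_glmm <- function(beta, data, spec, c_inst = NULL,
                               sigma0_sq = NULL) {
  stopifnot(inherits(spec, "glmm_spec"))
  if (!all(c("z", "n") %in% names(data))) {
    data <- aggregate_binomial(
      data, spec$predictors,
      institution = if (is.null(c_inst)) NULL else "institution_id"
    )
  }
  des <- glmm_design(data, spec, random_intercept = !is.null(c_inst))
  if (length(beta) != ncol(des$X))
    rlang::abort(sprintf("beta must have length %d (intercept + predictors)",
                         ncol(des$X)))
  eta <- drop(des$X %*% beta)
  if (!is.null(c_inst)) {
    if (length(c_inst) != des$n_inst)
      rlang::abort(sprintf("c_inst must have length %d (one per institution)",
                           des$n_inst))
    if (is.null(sigma0_sq) || length(sigma0_sq) != 1L)
      rlang::abort("sigma0_sq must be a single number for a random-intercept model")
    if (!is.finite(sigma0_sq) || sigma0_sq <= 0) return(-Inf)
    eta <- eta + c_inst[des$inst_idx]
  }
  lp <- glmm_loglik(eta, des$z, des$n) +
    sum(dnorm(beta, spec$fixed_prior_mean,
              sqrt(spec$fixed_prior_variance), log = TRUE))
  if (!is.null(c_inst))
    lp <- lp + sum(dnorm(c_inst, 0, sqrt(sigma0_sq), log = TRUE)) +
      dgamma(sigma0_sq, shape = spec$hyper_shape, rate = spec$hyper_rate,
             log = TRUE)
  lp
}

#' Generic random-walk Metropolis-Hastings chain
#'
#' Single-component random-walk sampler for an arbitrary log target, with
#' proposal scales adapted toward a target acceptance rate during burn-in only
#' (frozen afterwards, preserving detailed balance). Used internally for the
#' fixed-effect blocks and exposed for conjugate-oracle validation of the
#' sampler itself.
#'
#' @param log_target Function mapping a numeric state vector to its log
#'   density (up to a constant).
#' @param init Initial state vector.
#' @param n_iter Total iterations. Default 20000.
#' @param burn_in Iterations discarded (and used for adaptation). Default 500.
#' @param thin Keep every `thin`-th post-burn-in draw. Default 1.
#' @param scale Initial proposal standard deviations (recycled). Default 0.5.
#' @param seed RNG seed.
#' @param target_accept Acceptance rate targeted during adaptation. Default
#'   0.3.
#' @return A list with `draws` (matrix, one column per coordinate),
#'   `acceptance` (post-burn-in rate per coordinate) and `scale` (final
#'   proposal scales).
#' @export
mh_chain <- function(log_target, init, n_iter = 20000, burn_in = 500,
                     thin = 1, scale = 0.5, seed = 1, target_accept = 0.3) {
  if (n_iter <= burn_in || burn_in < 0)
    abort_config("n_iter", "must exceed burn_in (and burn_in must be >= 0)")
  d <- length(init)
  scale <- rep_len(scale, d)
  set.seed(seed)
  x <- init
  lp <- log_target(x)
  if (!is.finite(lp))
    rlang::abort("log target is not finite at the initial state; supply a valid init",
                 class = "preopbayes_init_error")
  keep <- floor((n_iter - burn_in) / thin)
  draws <- matrix(NA_real_, keep, d)
  acc <- numeric(d)
  acc_batch <- numeric(d)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    for (j in seq_len(d)) {
      prop <- x
      prop[j] <- x[j] + scale[j] * rnorm(1)
      lp_prop <- log_target(prop)
      if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
        x <- prop; lp <- lp_prop
        acc_batch[j] <- acc_batch[j] + 1
        if (it > burn_in) acc[j] <- acc[j] + 1
      }
    }
    if (it <= burn_in && it %% 50 == 0) {
      rate <- acc_batch / 50
      scale <- scale * exp(pmin(pmax(rate - target_accept, -0.5), 0.5))
      acc_batch[] <- 0
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- x
    }
  }
  list(draws = draws, acceptance = acc / (n_iter - burn_in), scale = scale)
}

# specialized sampler for the mixed model: single-site RW on each fixed
# effect, simultaneous independent RW on the (conditionally independent)
# institution intercepts, and log-scale RW with Jacobian on sigma0_sq
mh_glmm_chain <- function(des, spec, n_iter, burn_in, thin, seed,
                          target_accept = 0.3, keep_ranef = TRUE) {
  set.seed(seed)
  p <- ncol(des$X)
  random <- des$n_inst > 0L
  beta <- rep(0, p)
  c_inst <- rep(0, des$n_inst)
  sig2 <- 1

  # rough posterior-sd proposal scales from the curvature of the likelihood
  info_beta <- 0.25 * colSums(des$n * des$X^2) + 1 / spec$fixed_prior_variance
  s_beta <- 2.4 / sqrt(info_beta)
  if (random) {
    n_i <- as.numeric(rowsum(des$n, des$inst_idx))
    s_c <- 2.4 / sqrt(0.25 * n_i + 1)
  }
  s_v <- 0.5

  eta <- drop(des$X %*% beta)
  if (random) eta <- eta + c_inst[des$inst_idx]
  prior_beta <- function(b) dnorm(b, spec$fixed_prior_mean,
                                  sqrt(spec$fixed_prior_variance), log = TRUE)

  keep <- floor((n_iter - burn_in) / thin)
  beta_draws <- matrix(NA_real_, keep, p,
                       dimnames = list(NULL, colnames(des$X)))
  sig2_draws <- if (random) numeric(keep) else NULL
  c_draws <- if (random && keep_ranef) matrix(NA_real_, keep, des$n_inst) else NULL

  acc_beta <- numeric(p); acc_c <- 0; acc_v <- 0
  bat_beta <- numeric(p); bat_c <- 0; bat_v <- 0
  kept <- 0L
  ll <- glmm_loglik(eta, des$z, des$n)

  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      db <- s_beta[j] * rnorm(1)
      eta_prop <- eta + db * des$X[, j]
      ll_prop <- glmm_loglik(eta_prop, des$z, des$n)
      la <- ll_prop - ll + prior_beta(beta[j] + db) - prior_beta(beta[j])
      if (is.finite(la) && log(runif(1)) < la) {
        beta[j] <- beta[j] + db; eta <- eta_prop; ll <- ll_prop
        bat_beta[j] <- bat_beta[j] + 1
        if (it > burn_in) acc_beta[j] <- acc_beta[j] + 1
      }
    }
    if (random) {
      # institutions are conditionally independent given (beta, sigma0_sq):
      # propose all intercepts at once, accept each on its own likelihood slice
      dc <- s_c * rnorm(des$n_inst)
      eta_prop <- eta + dc[des$inst_idx]
      contrib <- des$z * eta - des$n * log1pexp(eta)
      contrib_prop <- des$z * eta_prop - des$n * log1pexp(eta_prop)
      dll_i <- as.numeric(rowsum(contrib_prop - contrib, des$inst_idx))
      dprior_i <- dnorm(c_inst + dc, 0, sqrt(sig2), log = TRUE) -
        dnorm(c_inst, 0, sqrt(sig2), log = TRUE)
      accept_i <- log(runif(des$n_inst)) < dll_i + dprior_i
      if (any(accept_i)) {
        c_inst[accept_i] <- c_inst[accept_i] + dc[accept_i]
        eta <- drop(des$X %*% beta) + c_inst[des$inst_idx]
        ll <- glmm_loglik(eta, des$z, des$n)
      }
      bat_c <- bat_c + mean(accept_i)
      if (it > burn_in) acc_c <- acc_c + mean(accept_i)

      # sigma0_sq on the log scale with Jacobian
      lsig_prop <- log(sig2) + s_v * rnorm(1)
      sig2_prop <- exp(lsig_prop)
      la <- sum(dnorm(c_inst, 0, sqrt(sig2_prop), log = TRUE)) -
        sum(dnorm(c_inst, 0, sqrt(sig2), log = TRUE)) +
        dgamma(sig2_prop, spec$hyper_shape, rate = spec$hyper_rate, log = TRUE) -
        dgamma(sig2, spec$hyper_shape, rate = spec$hyper_rate, log = TRUE) +
        lsig_prop - log(sig2)
      if (is.finite(la) && log(runif(1)) < la) {
        sig2 <- sig2_prop
        bat_v <- bat_v + 1
        if (it > burn_in) acc_v <- acc_v + 1
      }
    }
    if (it <= burn_in && it %% 50 == 0) {
      s_beta <- s_beta * exp(pmin(pmax(bat_beta / 50 - target_accept, -0.5), 0.5))
      if (random) {
        s_c <- s_c * exp(pmin(pmax(bat_c / 50 - target_accept, -0.5), 0.5))
        s_v <- s_v * exp(pmin(pmax(bat_v / 50 - target_accept, -0.5), 0.5))
      }
      bat_beta[] <- 0; bat_c <- 0; bat_v <- 0
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      beta_draws[kept, ] <- beta
      if (random) {
        sig2_draws[kept] <- sig2
        if (keep_ranef) c_draws[kept, ] <- c_inst
      }
    }
  }
  denom <- n_iter - burn_in
  list(
    beta = beta_draws, sigma0_sq = sig2_draws, c = c_draws,
    acceptance = c(
      setNames(acc_beta / denom, colnames(des$X)),
      if (random) c(c_inst = acc_c / denom, sigma0_sq = acc_v / denom)
    )
  )
}

#' Fit the Bayesian logistic mixed model by Metropolis-Hastings
#'
#' Component-block random-walk Metropolis-Hastings for the two-level logistic
#' model: single-site updates for each fixed effect, simultaneous independent
#' updates for the institution intercepts (conditionally independent given the
#' fixed effects and variance), and a log-scale update with Jacobian for the
#' random-intercept variance. Proposal scales adapt toward 20--40% acceptance
#' during burn-in only. Row-wise cohorts are aggregated to binomial sufficient
#' statistics first.
#'
#' @param data A cohort tibble (with `outcome`) or a pre-aggregated binomial
#'   table with `z` and `n` columns.
#' @param spec A [glmm_spec()], or `NULL` to build one from `predictors`.
#' @param predictors Predictor names, used when `spec` is `NULL`.
#' @param n_iter Total MCMC iterations per chain. Default 20000.
#' @param burn_in Burn-in iterations discarded. Default 500.
#' @param thin Thinning interval. Default 1.
#' @param chains Number of independent chains (seeds `seed`, `seed + 1`, ...).
#'   Default 1.
#' @param seed Integer RNG seed.
#' @param random_intercept Include institution random intercepts? Default
#'   `TRUE`.
#' @param keep_ranef Store the per-institution intercept draws? Default `TRUE`
#'   (disable for very large institution counts).
#' @return An object of class `preop_glmm` holding the chains, acceptance
#'   rates, spec and settings. Use [tidy()] for the odds-ratio table,
#'   [glance()] for fit-level summaries and [diagnose()] for convergence
#'   diagnostics.
#' @export
fit_glmm <- function(data, spec = NULL, predictors = NULL, n_iter = 20000,
                     burn_in = 500, thin = 1, chains = 1, seed = 1,
                     random_intercept = TRUE, keep_ranef = TRUE) {
  if (is.null(spec)) {
    if (is.null(predictors))
      rlang::abort("supply either a glmm_spec or a predictors vector")
    spec <- glmm_spec(predictors)
  }
  stopifnot(inherits(spec, "glmm_spec"))
  if (n_iter <= burn_in || burn_in < 0)
    abort_config("n_iter", "must exceed burn_in (and burn_in must be >= 0)")
  if (!all(c("z", "n") %in% names(data)))
    data <- aggregate_binomial(
      data, spec$predictors,
      institution = if (random_intercept) "institution_id" else NULL
    )
  des <- glmm_design(data, spec, random_intercept = random_intercept)
  fits <- lapply(seq_len(chains), function(k)
    mh_glmm_chain(des, spec, n_iter, burn_in, thin, seed = seed + k - 1L,
                  keep_ranef = keep_ranef))
  structure(
    list(chains = fits, spec = spec,
         settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                         chains = chains, seed = seed,
                         random_intercept = random_intercept),
         data_info = list(n_obs = sum(des$n), n_rows = nrow(des$X),
                          n_institutions = des$n_inst),
         institution_levels = if (!is.null(des$inst)) levels(des$inst)),
    class = "preop_glmm"
  )
}

# pooled post-burn-in draws of one fixed-effect (or variance) parameter
pooled_draws <- function(fit, parameter) {
  if (parameter == "sigma0_sq")
    return(unlist(lapply(fit$chains, `[[`, "sigma0_sq"), use.names = FALSE))
  unlist(lapply(fit$chains, function(ch) ch$beta[, parameter]),
         use.names = FALSE)
}

#' @export
print.preop_glmm <- function(x, ...) {
  cat(sprintf(
    "Bayesian logistic %s (MH): %d chain(s) x %d iterations (burn-in %d, thin %d)\n",
    if (x$settings$random_intercept) "mixed model" else "model",
    x$settings$chains, x$settings$n_iter, x$settings$burn_in, x$settings$thin))
  cat(sprintf("  %d observations in %d aggregated rows",
              x$data_info$n_obs, x$data_info$n_rows))
  if (x$settings$random_intercept)
    cat(sprintf(", %d institutions", x$data_info$n_institutions))
  cat("\n")
  print(tidy(x))
  invisible(x)
}

#' Highest-posterior-density interval of a sample
#'
#' Narrowest contiguous interval containing the requested fraction of the
#' sorted draws (the Chen--Shao sliding window over order statistics).
#'
#' @param samples Numeric vector of at least 100 posterior draws.
#' @param level Interval mass in (0, 1). Default 0.95.
#' @return A one-row tibble with `lower`, `upper`, `level`, `kind = "HPD"`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 100)
    rlang::abort("at least 100 samples are required for an HPD interval",
                 class = "preopbayes_insufficient_samples_error")
  if (length(level) != 1L || level <= 0 || level >= 1)
    abort_config("level", "must be a probability strictly between 0 and 1")
  x <- sort(samples)
  gap <- max(1L, min(n - 1L, round(n * level)))
  widths <- x[(1L + gap):n] - x[1:(n - gap)]
  i <- which.min(widths)
  tibble(lower = x[i], upper = x[i + gap], level = level, kind = "HPD")
}

#' Posterior odds-ratio summary of a fitted model
#'
#' One row per fixed effect: the posterior mean on the log-odds scale, its
#' posterior standard deviation, the odds ratio `exp(posterior mean)`, and the
#' HPD interval computed on the log-odds scale then exponentiated
#' (order-preserving). Chains are pooled.
#'
#' @param x A `preop_glmm` fit.
#' @param conf.level HPD mass. Default 0.95.
#' @param effects `"fixed"` (default) for the coefficient table, `"ran_pars"`
#'   for the random-intercept variance summary.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `odds.ratio`, `conf.low`, `conf.high` (OR scale), `conf.level`.
#' @export
tidy.preop_glmm <- function(x, conf.level = 0.95, effects = "fixed", ...) {
  if (identical(effects, "ran_pars")) {
    if (!x$settings$random_intercept)
      return(tibble(term = character(), estimate = numeric()))
    draws <- pooled_draws(x, "sigma0_sq")
    hpd <- hpd_interval(draws, conf.level)
    return(tibble(term = "sigma0_sq", estimate = mean(draws),
                  std.error = sd(draws), conf.low = hpd$lower,
                  conf.high = hpd$upper, conf.level = conf.level))
  }
  terms <- colnames(x$chains[[1]]$beta)
  purrr::map_dfr(terms, function(tm) {
    draws <- pooled_draws(x, tm)
    hpd <- hpd_interval(draws, conf.level)
    tibble(term = tm, estimate = mean(draws), std.error = sd(draws),
           odds.ratio = exp(mean(draws)), conf.low = exp(hpd$lower),
           conf.high = exp(hpd$upper), conf.level = conf.level)
  })
}

#' @rdname tidy.preop_glmm
#' @export
glance.preop_glmm <- function(x, ...) {
  acc <- unlist(lapply(x$chains, `[[`, "acceptance"))
  tibble(
    n_obs = x$data_info$n_obs,
    n_institutions = x$data_info$n_institutions,
    chains = x$settings$chains,
    n_iter = x$settings$n_iter,
    burn_in = x$settings$burn_in,
    thin = x$settings$thin,
    draws_retained = x$settings$chains *
      floor((x$settings$n_iter - x$settings$burn_in) / x$settings$thin),
    mean_acceptance = mean(acc)
  )
}

#' Univariate Bayesian logistic fit of the bed-size effect
#'
#' Fits `logit(pi) = b0 + b1 * I(beds >= 100)` with the mixed model's
#' fixed-effect priors and no random effects, directly on the binomial
#' sufficient statistics of a two-by-two table. A zero margin triggers a
#' warning (the normal priors keep the posterior proper) but the fit proceeds.
#'
#' @param tab A [two_by_two()] object.
#' @param spec Optional [glmm_spec()]; default builds one for `beds_ge_100`.
#' @param n_iter,burn_in,thin,chains,seed MCMC settings passed to
#'   [fit_glmm()]. Defaults 20000, 500, 1, 1, 1.
#' @return A `preop_glmm` fit; `tidy()` reports the bed-size odds ratio.
#' @examples
#' \donttest{
#' fit <- univariate_fit(example_bedsize_counts(), n_iter = 4000)
#' tidy(fit)
#' }
#' @export
univariate_fit <- function(tab, spec = NULL, n_iter = 20000, burn_in = 500,
                           thin = 1, chains = 1, seed = 1) {
  stopifnot(inherits(tab, "two_by_two"))
  if (any(tab$z == 0) || any(tab$n - tab$z == 0))
    rlang::warn("a margin of the 2x2 table is zero; priors regularize the fit")
  agg <- tibble(
    beds_ge_100 = as.numeric(tab$group == "large"),
    z = tab$z, n = tab$n
  )
  spec <- spec %||% glmm_spec("beds_ge_100")
  fit_glmm(agg, spec = spec, n_iter = n_iter, burn_in = burn_in, thin = thin,
           chains = chains, seed = seed, random_intercept = FALSE)
}
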