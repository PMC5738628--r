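#' Conjugate beta-binomial posterior update for both bed-size groups
#'
#' With a Beta(alpha, beta) prior on each group's testing probability and `z`
#' positives out of `n` surgeries, the posterior is Beta(alpha + z,
#' n - z + beta). The default Beta(1, 1) prior is uniform (noninformative).
#'
#' @param counts A [two_by_two()] object.
#' @param prior_alpha,prior_beta Shape parameters of the beta prior shared by
#'   both groups. Must be positive. Defaults 1 and 1.
#' @return A tibble of class `beta_posteriors` with one row per group and
#'   columns `group`, `z`, `n`, `alpha`, `beta` (posterior shapes) and `mean`
#'   (posterior mean `alpha / (alpha + beta)`).
#' @examples
#' beta_update(example_bedsize_counts())
#' @export
beta_update <- function(counts, prior_alpha = 1, prior_beta = 1) {
  stopifnot(inherits(counts, "two_by_two"))
  if (length(prior_alpha) != 1L || !is.finite(prior_alpha) || prior_alpha <= 0)
    abort_config("prior_alpha", "must be a single positive number")
  if (length(prior_beta) != 1L || !is.finite(prior_beta) || prior_beta <= 0)
    abort_config("prior_beta", "must be a single positive number")
  if (any(counts$z < 0) || any(counts$z > counts$n))
    rlang::abort("counts must satisfy 0 <= z <= n in each group",
                 class = "preopbayes_domain_error")
  out <- dplyr::mutate(
    as_tibble(counts),
    alpha = prior_alpha + .data$z,
    beta = (.data$n - .data$z) + prior_beta,
    mean = .data$alpha / (.data$alpha + .data$beta)
  )
  class(out) <- c("beta_posteriors", class(out))
  out
}

posterior_row <- function(post, group) {
  stopifnot(inherits(post, "beta_posteriors"))
  row <- post[post$group == group, , drop = FALSE]
  if (nrow(row) != 1L)
    rlang::abort(sprintf("posteriors table must have exactly one `%s` row", group))
  row
}

beta_var <- function(a, b) a * b / ((a + b)^2 * (a + b + 1))

#' Posterior mean of the difference in testing rates
#'
#' Expectation of `D = p_large - p_small` under independent beta posteriors;
#' by linearity this equals the difference of the two posterior means.
#'
#' @param post A `beta_posteriors` table from [beta_update()].
#' @return A single number in `[-1, 1]`.
#' @export
diff_mean <- function(post) {
  l <- posterior_row(post, "large")
  s <- posterior_row(post, "small")
  l$mean - s$mean
}

# log-space beta density; a, b may be ~2e4 so everything goes through lbeta
dbeta_log <- function(x, a, b) {
  ifelse(x > 0 & x < 1,
         (a - 1) * log(x) + (b - 1) * log1p(-x) - lbeta(a, b),
         -Inf)
}

# density of D = pL - pS at a scalar d by 1-D quadrature over the overlap of
# the two (numerically truncated) beta supports
diff_density_at <- function(d, aL, bL, aS, bS, q = 1e-12) {
  lo <- max(qbeta(q, aL, bL), d + qbeta(q, aS, bS), d, 0)
  hi <- min(qbeta(q, aL, bL, lower.tail = FALSE),
            d + qbeta(q, aS, bS, lower.tail = FALSE), 1, 1 + d)
  if (lo >= hi) return(0)
  f <- function(x) exp(dbeta_log(x, aL, bL) + dbeta_log(x - d, aS, bS))
  res <- tryCatch(
    integrate(f, lo, hi, rel.tol = 1e-9, subdivisions = 400L, stop.on.error = FALSE),
    error = function(e) NULL
  )
  if (is.null(res))
    rlang::abort("quadrature failed while evaluating the difference density",
                 class = "preopbayes_numerical_error")
  res$value
}

diff_grid <- function(post, resolution) {
  l <- posterior_row(post, "large")
  s <- posterior_row(post, "small")
  m <- l$mean - s$mean
  sdD <- sqrt(beta_var(l$alpha, l$beta) + beta_var(s$alpha, s$beta))
  half <- max(8 * sdD, 1e-6)
  d <- seq(max(-1, m - half), min(1, m + half), length.out = resolution)
  dens <- vapply(d, diff_density_at, numeric(1),
                 aL = l$alpha, bL = l$beta, aS = s$alpha, bS = s$beta)
  tibble(d = d, density = dens)
}

#' Tabulated density of the difference of the two group rates
#'
#' Computes the density of `D = p_large - p_small` on a regular grid by
#' numerical convolution of the two beta posterior densities (one-dimensional
#' quadrature per grid point, with densities evaluated in log space so shape
#' parameters of order 1e4 do not overflow). The grid spans +/- 8 posterior
#' standard deviations of `D` around the point estimate, clipped to `[-1, 1]`.
#'
#' @param post A `beta_posteriors` table from [beta_update()].
#' @param resolution Number of grid points, at least 16. Default 4097.
#' @return A tibble with columns `d` and `density`; the trapezoid integral of
#'   `density` over `d` is 1 up to quadrature error.
#' @export
diff_density <- function(post, resolution = 4097) {
  if (length(resolution) != 1L || !is.numeric(resolution) || resolution < 16)
    abort_config("resolution", "must be a single number >= 16")
  diff_grid(post, as.integer(resolution))
}

trapezoid_cdf <- function(d, dens) {
  inc <- diff(d) * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2
  cdf <- c(0, cumsum(inc))
  list(total = cdf[length(cdf)], cdf = cdf)
}

invert_cdf <- function(d, cdf, p) {
  # monotone linear interpolation of the first crossing
  stats::approx(cdf, d, xout = p, ties = "ordered")$y
}

#' Equal-tailed credible interval for the difference in testing rates
#'
#' Inverts the numerically-convolved cumulative distribution of
#' `D = p_large - p_small` (see [diff_density()]) at the equal-tail
#' probabilities. The grid is refined (resolution doubled) until both interval
#' endpoints move by less than `refine_tol` between refinements.
#'
#' @param post A `beta_posteriors` table from [beta_update()].
#' @param level Credibility level in (0, 1). Default 0.95.
#' @param resolution Initial grid resolution. Default 1025.
#' @param refine_tol Convergence tolerance for the interval endpoints across
#'   grid refinements. Default 1e-5.
#' @return An object of class `rate_difference`: a list with `estimate` (the
#'   posterior mean of `D`), `lower`, `upper`, `level`, `kind =
#'   "equal-tailed"`, the final density grid, and the resolution used.
#'   [tidy()] turns it into a one-row tibble.
#' @examples
#' post <- beta_update(example_bedsize_counts())
#' rate_difference(post)
#' @export
rate_difference <- function(post, level = 0.95, resolution = 1025,
                            refine_tol = 1e-5) {
  if (length(level) != 1L || !is.numeric(level) || level <= 0 || level >= 1)
    abort_config("level", "must be a probability strictly between 0 and 1")
  if (length(resolution) != 1L || !is.numeric(resolution) || resolution < 16)
    abort_config("resolution", "must be a single number >= 16")
  tails <- c((1 - level) / 2, 1 - (1 - level) / 2)
  res <- as.integer(resolution)
  prev <- c(-Inf, Inf)
  grid <- NULL
  for (round in 1:5) {
    grid <- diff_grid(post, res)
    tc <- trapezoid_cdf(grid$d, grid$density)
    if (abs(tc$total - 1) > 1e-4)
      rlang::abort(sprintf(
        "difference density integrates to %.6f, not 1: quadrature did not converge",
        tc$total), class = "preopbayes_numerical_error")
    ends <- invert_cdf(grid$d, tc$cdf / tc$total, tails)
    if (any(!is.finite(ends)))
      rlang::abort("credible-interval endpoints fell outside the density grid",
                   class = "preopbayes_numerical_error")
    if (max(abs(ends - prev)) < refine_tol) break
    prev <- ends
    res <- 2L * res - 1L
  }
  structure(
    list(estimate = diff_mean(post), lower = ends[1], upper = ends[2],
         level = level, kind = "equal-tailed", density = grid,
         resolution = res, posteriors = post),
    class = "rate_difference"
  )
}

#' @export
print.rate_difference <- function(x, ...) {
  cat(sprintf(
    "Difference in testing rates (large - small): %.3f [%g%% CrI %.3f to %.3f]\n",
    x$estimate, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' @rdname rate_difference
#' @param x A `rate_difference` object.
#' @param ... Unused.
#' @export
tidy.rate_difference <- function(x, ...) {
  tibble(
    estimate = x$estimate, conf.low = x$lower, conf.high = x$upper,
    conf.level = x$level, kind = x$kind, method = "numerical convolution"
  )
}

#' Monte Carlo check of the rate-difference interval
#'
#' Draws paired independent beta samples and returns empirical equal-tailed
#' quantiles of the difference; used as a stochastic oracle for
#' [rate_difference()].
#'
#' @param post A `beta_posteriors` table.
#' @param level Credibility level. Default 0.95.
#' @param n_draws Number of paired draws. Default 1e6.
#' @param seed RNG seed.
#' @return A one-row tibble with `estimate`, `conf.low`, `conf.high`.
#' @export
rate_difference_mc <- function(post, level = 0.95, n_draws = 1e6, seed = 1) {
  l <- posterior_row(post, "large")
  s <- posterior_row(post, "small")
  set.seed(seed)
  dd <- rbeta(n_draws, l$alpha, l$beta) - rbeta(n_draws, s$alpha, s$beta)
  qq <- unname(quantile(dd, probs = c((1 - level) / 2, 1 - (1 - level) / 2)))
  tibble(estimate = mean(dd), conf.low = qq[1], conf.high = qq[2])
}
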