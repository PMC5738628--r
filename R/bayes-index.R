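# Kawasaki-Miyaoka index for two beta posteriors.
#
# The exact series computes P(pA > pB) for pA ~ Beta(aA, bA), pB ~ Beta(aB, bB):
#
#   P(pA > pB) = B(aA+aB, bA) / (aB * B(aA,bA) * B(aB,bB))
#                * 3F2(aB, 1-bB, aA+aB; 1+aB, aA+aB+bA; 1)
#
# The user-facing index is always oriented as theta = P(p_small < p_large),
# which equals P(pA > pB) with A = large, B = small.

# One step of the 3F2 term recursion: term_{t+1} / term_t.
km_term_ratio <- function(t, aA, bA, aB, bB) {
  ((aB + t) * (1 - bB + t) * (aA + aB + t)) /
    ((1 + aB + t) * (aA + aB + bA + t) * (1 + t))
}

# P(pA > pB) by term-by-term summation of the 3F2 series. Terms are tracked as
# (sign, log magnitude); positive and negative parts are accumulated separately
# in log space and differenced at the end, so that catastrophic cancellation is
# detectable rather than silent.
km_series <- function(aA, bA, aB, bB, tol = 1e-10, max_terms = 1e6) {
  lpref <- lbeta(aA + aB, bA) - log(aB) - lbeta(aA, bA) - lbeta(aB, bB)
  # integer bB terminates the series: (1-bB)_t = 0 for t >= bB
  terminating <- abs(bB - round(bB)) < 1e-12
  term_cap <- if (terminating) round(bB) else max_terms

  lpos <- 0        # term 0 is +1
  lneg <- -Inf
  lterm <- 0
  sgn <- 1
  lmax <- 0
  t <- 0
  bound <- Inf
  repeat {
    ratio <- km_term_ratio(t, aA, bA, aB, bB)
    t <- t + 1
    if (ratio == 0 || t >= term_cap) { bound <- 0; break }
    lterm <- lterm + log(abs(ratio))
    sgn <- sgn * sign(ratio)
    lmax <- max(lmax, lterm)
    # theta <= 1 bounds the true sum by exp(-lpref); an alternating term 25
    # log-units above that guarantees fatal cancellation -- bail out early
    if (bB > 1 && lterm > -lpref + 25)
      rlang::abort(
        "3F2 series lost all precision to alternating-term cancellation; use theta_quadrature()",
        class = "preopbayes_series_error"
      )
    if (sgn > 0) lpos <- logsumexp(c(lpos, lterm)) else lneg <- logsumexp(c(lneg, lterm))
    # geometric tail bound once term magnitudes are decaying
    r <- abs(km_term_ratio(t, aA, bA, aB, bB))
    if (r < 1) {
      lsum_abs <- max(lpos, lneg)
      bound <- exp(lterm + log(r) - log1p(-r) - lsum_abs)
      if (bound < tol) break
    }
    if (t >= max_terms)
      rlang::abort(
        sprintf("3F2 series did not converge within %d terms; use theta_quadrature()", max_terms),
        class = "preopbayes_series_error"
      )
  }
  if (lneg > lpos)
    rlang::abort("3F2 series summed to a negative value (cancellation); use theta_quadrature()",
                 class = "preopbayes_series_error")
  lsum <- lpos + log1p(-exp(lneg - lpos))
  # cancellation between the positive and negative parts: the computed sum
  # carries an absolute rounding error of order eps * exp(lpos), so once the
  # accumulated magnitude exceeds the result by ~25 log-units (~11 decimal
  # digits) the value is untrustworthy
  if (!is.finite(lsum) || (lpos - lsum) > 25)
    rlang::abort(
      "3F2 series lost all precision to alternating-term cancellation; use theta_quadrature()",
      class = "preopbayes_series_error"
    )
  list(value = exp(lpref + lsum), terms_used = t, truncation_bound = max(bound, 0))
}

# P(pX < pY) for integer aY via the finite positive-term rearrangement of the
# hypergeometric series,
#   P(pX < pY) = sum_{i=0}^{aY-1} B(aX+i, bX+bY) / ((bY+i) B(1+i, bY) B(aX, bX)),
# algebraically equivalent to Eq-2-style summation but free of alternating
# signs, hence stable at posterior sample sizes in the tens of thousands.
# Everything is evaluated through log-beta and combined with one log-sum-exp.
km_positive_sum <- function(aX, bX, aY, bY) {
  i <- seq_len(round(aY)) - 1
  lt <- lbeta(aX + i, bX + bY) - log(bY + i) - lbeta(1 + i, bY) - lbeta(aX, bX)
  list(value = exp(logsumexp(lt)), terms_used = length(i), truncation_bound = 0)
}

theta_result <- function(theta, method, terms_used = NA_integer_,
                         truncation_bound = NA_real_, mc_se = NA_real_) {
  tibble(theta = theta, method = method, terms_used = terms_used,
         truncation_bound = truncation_bound, mc_se = mc_se)
}

check_shapes <- function(a_small, b_small, a_large, b_large) {
  v <- c(a_small = a_small, b_small = b_small, a_large = a_large, b_large = b_large)
  for (nm in names(v))
    if (length(v[[nm]]) != 1L || !is.finite(v[[nm]]) || v[[nm]] <= 0)
      abort_config(nm, "must be a single positive number")
}

#' Exact Bayesian index for two beta posteriors (3F2 series)
#'
#' Evaluates `theta = P(p_small < p_large)` for independent
#' `p_small ~ Beta(a_small, b_small)` and `p_large ~ Beta(a_large, b_large)` by
#' term-by-term summation of the generalized hypergeometric series, with all
#' beta-function and Pochhammer factors accumulated in log space and each term
#' obtained from the previous one by a rational ratio. When the second shape of
#' the conditioning group is a positive integer the series terminates and the
#' truncation bound is exactly zero.
#'
#' The series alternates in sign whenever that second shape exceeds 1, and for
#' large shape parameters (posterior sample sizes in the tens of thousands) the
#' intermediate terms dwarf the result, destroying all double-precision
#' accuracy. The function detects this (it never returns a silently wrong
#' value) and recovers exactly when either first shape is a positive integer
#' -- the case for any posterior built from count data with an integer prior
#' shape -- by summing the algebraically equivalent finite series with all
#' positive terms. Otherwise it raises a classed error
#' (`preopbayes_series_error`) recommending [theta_quadrature()]. The direct
#' orientation is tried first and the complementary orientation
#' (`1 - P(p_small > p_large)`) second.
#'
#' @param a_small,b_small Posterior shape parameters of the <100-bed group.
#' @param a_large,b_large Posterior shape parameters of the >=100-bed group.
#' @param tol Relative tail-bound tolerance for series truncation, in
#'   `(0, 1e-3]`. Default 1e-10.
#' @param max_terms Term cap before declaring non-convergence. Default 1e6.
#' @return A one-row tibble with `theta`, `method = "exact-series"`,
#'   `terms_used` and `truncation_bound`.
#' @examples
#' theta_exact(3, 9, 9, 3)
#' @export
theta_exact <- function(a_small, b_small, a_large, b_large,
                        tol = 1e-10, max_terms = 1e6) {
  check_shapes(a_small, b_small, a_large, b_large)
  if (length(tol) != 1L || !is.numeric(tol) || tol <= 0 || tol > 1e-3)
    abort_config("tol", "must be in (0, 1e-3]")
  # series convergence condition k1+k2+k3 < l1+l2 reduces to -bB < bA
  stopifnot(-b_small < b_large, -b_large < b_small)
  direct <- tryCatch(
    km_series(a_large, b_large, a_small, b_small, tol, max_terms),
    preopbayes_series_error = function(e) e
  )
  if (!inherits(direct, "condition"))
    return(theta_result(min(max(direct$value, 0), 1), "exact-series",
                        direct$terms_used, direct$truncation_bound))
  flipped <- tryCatch(
    km_series(a_small, b_small, a_large, b_large, tol, max_terms),
    preopbayes_series_error = function(e) e
  )
  if (!inherits(flipped, "condition"))
    return(theta_result(min(max(1 - flipped$value, 0), 1), "exact-series",
                        flipped$terms_used, flipped$truncation_bound))
  # alternating-sign summation is hopeless at these magnitudes; for integer
  # shapes the finite positive-term rearrangement is exact and stable
  int_ok <- function(a) abs(a - round(a)) < 1e-9 && round(a) >= 1 && round(a) <= max_terms
  if (int_ok(a_large)) {
    res <- km_positive_sum(a_small, b_small, a_large, b_large)
    return(theta_result(min(max(res$value, 0), 1), "exact-series",
                        res$terms_used, res$truncation_bound))
  }
  if (int_ok(a_small)) {
    res <- km_positive_sum(a_large, b_large, a_small, b_small)
    return(theta_result(min(max(1 - res$value, 0), 1), "exact-series",
                        res$terms_used, res$truncation_bound))
  }
  rlang::abort(conditionMessage(direct), class = "preopbayes_series_error")
}

#' Bayesian index by adaptive quadrature
#'
#' Computes `theta = P(p_small < p_large)` as the integral of the large-group
#' beta density times the small-group beta CDF, over the numerically relevant
#' support of the large-group posterior. Serves as the robust cross-check (and
#' fallback) for [theta_exact()] at any shape magnitudes.
#'
#' @inheritParams theta_exact
#' @param tol Requested relative accuracy (floored at 1e-12). Default 1e-10.
#' @return A one-row tibble with `theta` and `method = "quadrature"`.
#' @examples
#' theta_quadrature(2, 1, 1, 1)  # P(p1 < p2) = 1/3
#' @export
theta_quadrature <- function(a_small, b_small, a_large, b_large, tol = 1e-10) {
  check_shapes(a_small, b_small, a_large, b_large)
  f <- function(x) dbeta(x, a_large, b_large) * pbeta(x, a_small, b_small)
  lo <- qbeta(1e-14, a_large, b_large)
  hi <- qbeta(1e-14, a_large, b_large, lower.tail = FALSE)
  res <- tryCatch(
    integrate(f, lo, hi, rel.tol = max(tol, 1e-12), subdivisions = 400L),
    error = function(e)
      rlang::abort(paste0("quadrature for the Bayesian index failed: ",
                          conditionMessage(e)),
                   class = "preopbayes_numerical_error")
  )
  theta_result(min(max(res$value, 0), 1), "quadrature")
}

#' Bayesian index by Monte Carlo
#'
#' Stochastic oracle: the fraction of paired independent posterior draws with
#' `p_small < p_large`, with its binomial standard error.
#'
#' @inheritParams theta_exact
#' @param n_draws Number of paired draws, at least 1000. Default 1e6.
#' @param seed RNG seed.
#' @return A one-row tibble with `theta`, `method = "monte-carlo"` and `mc_se`.
#' @export
theta_mc <- function(a_small, b_small, a_large, b_large,
                     n_draws = 1e6, seed = 1) {
  check_shapes(a_small, b_small, a_large, b_large)
  if (n_draws < 1e3) abort_config("n_draws", "must be at least 1000")
  set.seed(seed)
  hit <- mean(rbeta(n_draws, a_small, b_small) < rbeta(n_draws, a_large, b_large))
  theta_result(hit, "monte-carlo", mc_se = sqrt(hit * (1 - hit) / n_draws))
}

#' Bayesian index that one group's testing rate exceeds the other's
#'
#' User-facing wrapper around [theta_exact()], [theta_quadrature()] and
#' [theta_mc()] operating on the posterior table from [beta_update()]. The
#' index is always oriented as `theta = P(p_small < p_large)`. With
#' `method = "auto"` the exact series is attempted first and quadrature is used
#' when the series is numerically infeasible at the given shape magnitudes.
#'
#' @param post A `beta_posteriors` table from [beta_update()].
#' @param method One of `"auto"`, `"exact"`, `"quadrature"`, `"mc"`.
#' @param tol Series / quadrature tolerance. Default 1e-10.
#' @param n_draws,seed Monte Carlo settings (used when `method = "mc"`).
#' @return A one-row tibble with `theta`, `method`, `terms_used`,
#'   `truncation_bound`, `mc_se` and the orientation label.
#' @examples
#' bayes_index(beta_update(example_bedsize_counts()))
#' @export
bayes_index <- function(post, method = c("auto", "exact", "quadrature", "mc"),
                        tol = 1e-10, n_draws = 1e6, seed = 1) {
  method <- match.arg(method)
  s <- posterior_row(post, "small")
  l <- posterior_row(post, "large")
  res <- switch(
    method,
    exact = theta_exact(s$alpha, s$beta, l$alpha, l$beta, tol = tol),
    quadrature = theta_quadrature(s$alpha, s$beta, l$alpha, l$beta, tol = tol),
    mc = theta_mc(s$alpha, s$beta, l$alpha, l$beta, n_draws = n_draws, seed = seed),
    auto = tryCatch(
      theta_exact(s$alpha, s$beta, l$alpha, l$beta, tol = tol),
      preopbayes_series_error = function(e)
        theta_quadrature(s$alpha, s$beta, l$alpha, l$beta, tol = tol)
    )
  )
  dplyr::mutate(res, orientation = "P(p_small < p_large)")
}
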