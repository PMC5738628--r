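---
title: "Bayesian comparison of preoperative testing rates between institution groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian comparison of preoperative testing rates between institution groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preopbayes)
```

## The problem

Routine blood testing before low-risk surgery (cataract extraction, superficial
excisions, arthroscopy, minor gynecologic or urologic procedures) is discouraged
by multiple specialty societies, yet remains common. Claims databases make it
possible to ask *where* the excess testing concentrates: with the patient, or
with the institution. `preopbayes` implements the Bayesian toolkit for that
question on cohorts of surgeries clustered within institutions:

1. a **conjugate beta-binomial comparison** of the testing rate between
   institutions with fewer than 100 beds and those with 100 or more — the
   threshold used to classify general hospitals in Japan;
2. the **exact Bayesian index** $\theta = P(p_\text{small} < p_\text{large}
   \mid z_1, z_2)$, the posterior probability that the large-bed testing rate
   exceeds the small-bed rate;
3. a **two-level Bayesian logistic mixed model** with institution random
   intercepts, fitted by random-walk Metropolis–Hastings and summarized as
   odds ratios with highest-posterior-density (HPD) intervals;
4. **convergence diagnostics** (autocorrelation, effective sample size, split
   R-hat) for the MCMC output; and
5. a **synthetic claims-cohort generator**, because the motivating data source
   is a proprietary employment-based claims database that cannot be shipped.

## The two-group conjugate model

Let $Z_g \sim \mathrm{Binomial}(n_g, p_g)$ count tested surgeries in bed-size
group $g \in \{\text{small}, \text{large}\}$. With independent
$\mathrm{Beta}(\alpha, \beta)$ priors, the posteriors are
$p_g \mid z_g \sim \mathrm{Beta}(\alpha + z_g,\; n_g - z_g + \beta)$. The
default prior is the uniform $\mathrm{Beta}(1,1)$.

```{r}
counts <- example_bedsize_counts()
counts
post <- beta_update(counts)
post
```

### Credible interval for the difference

The posterior of $D = p_\text{large} - p_\text{small}$ has no standard closed
form; `rate_difference()` computes its density by one-dimensional numerical
convolution of the two beta densities (one quadrature per grid point, densities
evaluated in log space via `lbeta()` so shapes of order $2\times 10^4$ do not
overflow), then inverts the trapezoid CDF at the equal-tail probabilities.

Numerical choices: the grid spans $\pm 8$ posterior standard deviations of $D$
around the point estimate (mass outside is below $10^{-14}$), starts at 1,025
points, and doubles until both endpoints move by less than $10^{-5}$; the
density must integrate to 1 within $10^{-4}$ or the call fails loudly. The
interval is **equal-tailed**, not HPD: the analysis tradition this package
follows reserves HPD summaries for the regression model and reports the
two-group contrast as a central credible interval. For these unimodal,
near-symmetric posteriors the two differ by far less than display precision.
A Monte Carlo cross-check (`rate_difference_mc()`, paired beta draws) is kept
as an independent oracle in the test suite rather than as the implementation.

```{r}
rd <- rate_difference(post)
rd
```

### The Bayesian index

The index $\theta = P(p_1 < p_2 \mid z_1, z_2)$ has an exact representation as
a beta-function prefactor times a generalized hypergeometric series
$_3F_2(a_2,\, 1-b_2,\, a_1+a_2;\; 1+a_2,\; a_1+a_2+b_1;\; 1)$, summed by
recursive term ratios with all Pochhammer and beta factors in log space.
Two numerical facts shape the implementation:

* when $b_2$ is a positive integer the factor $(1-b_2)_t$ vanishes for
  $t \ge b_2$, so the series **terminates** and the truncation bound is exactly
  zero — the implementation detects and exploits this;
* for $b_2 > 1$ the terms **alternate in sign**, and at posterior sample sizes
  in the thousands they grow by orders of magnitude before decaying. The true
  sum is then smaller than the largest term by hundreds of log-units, which no
  double-precision accumulation can survive. The series code tracks positive
  and negative parts separately and *fails loudly* (a classed error) instead of
  returning a cancelled-to-noise value.

When either $a$ parameter is a positive integer — always the case for
posteriors built from count data with integer prior shapes — the identity
$$P(p_1 < p_2) = \sum_{i=0}^{a_2-1}
\frac{B(a_1+i,\; b_1+b_2)}{(b_2+i)\; B(1+i,\; b_2)\; B(a_1, b_1)}$$
rearranges the same quantity into a finite sum with **all positive terms**,
stable at any magnitude; `theta_exact()` falls through to it automatically.
For non-integer shapes at large magnitude no stable exact series exists in
double precision, and `theta_quadrature()` (integration of one beta density
against the other's CDF) is the robust route; `bayes_index(method = "auto")`
handles the dispatch. `theta_mc()` is a stochastic oracle with a reported
standard error. The index is always reported as
$P(p_\text{small} < p_\text{large})$ with explicit group labels, because
subscript conventions for the two groups are easy to flip.

```{r}
bayes_index(post, method = "exact")
```

## The logistic mixed model

For surgery $j$ at institution $i$, the outcome $Y_{ij}$ (any of CBC, basic
metabolic panel, coagulation test, or liver function test ordered within the
preoperative window) follows
$$\log\frac{\pi_{ij}}{1-\pi_{ij}} = \beta_0 + \beta_1 x_{1ij} + \cdots +
\beta_p x_{pij} + c_i, \qquad
\beta_k \sim N(0, 1000), \quad c_i \sim N(0, \sigma_0^2).$$

**Fixed-effect prior variance.** The source analysis states the prior variance
ambiguously (1,000 in the model display, 10,000 in the text). The default here
is 1,000, exposed as `fixed_prior_variance`; at these data sizes the likelihood
dominates and the two are indistinguishable in practice.

**Hyperprior parameterization.** The variance hyperprior is written
"Gamma(0.001, 0.001)". Read as (shape, *scale*) this is a distribution with
mean $10^{-6}$ and an $e^{-1000\sigma_0^2}$ tail that would pin the
random-intercept variance at zero regardless of the data — no mixed model could
recover $\sigma_0^2 = 0.25$ under it. Read as (shape, *rate*), the convention of
the SAS procedure the original analysis used and of vague variance priors
generally, it has mean 1 and variance 1,000. `glmm_spec()` therefore defaults
to `hyper_shape = 0.001`, `hyper_rate = 0.001`; both are configurable. The
package's parameter-recovery tests (posterior mean of $\sigma_0^2$ within 50%
of truth at 200 institutions) validate this choice.

**Sampler.** Row-wise cohorts are first aggregated to binomial sufficient
statistics per (institution × covariate pattern) — an exact identity for the
Bernoulli likelihood, verified against a row-wise oracle in the tests. The
sampler is component-block random-walk Metropolis–Hastings: single-site updates
per fixed effect; *simultaneous independent* updates of all institution
intercepts (valid because the $c_i$ are conditionally independent given
$\beta, \sigma_0^2$, and each proposal is accepted on its own likelihood
slice); and a log-scale update with Jacobian for $\sigma_0^2$. Proposal scales
start at curvature-based guesses and adapt toward 20–40% acceptance in batches
of 50 iterations **during burn-in only**, so the post-burn-in kernel satisfies
detailed balance. Defaults mirror the source analysis: 20,000 iterations, 500
burn-in, thin 1, one chain; initialization is $\beta = 0$, $c = 0$,
$\sigma_0^2 = 1$. Multiple chains (`chains =`) and thinning are available
because random-walk MH output here is strongly autocorrelated — the
diagnostics module quantifies what the original work judged by eye, flagging
ESS below 100 or split R-hat above 1.05 (package policy, configurable).

Summaries follow the odds-ratio convention: posterior mean of $\beta_k$,
exponentiated; HPD intervals computed on the $\beta$ scale by the Chen–Shao
minimal-width window over order statistics, then exponentiated
(order-preserving).

```{r, eval = FALSE}
fit <- fit_glmm(cohort, predictors = c("female", "outpatient", "beds_ge_100"),
                n_iter = 20000, burn_in = 500, chains = 3, seed = 1)
tidy(fit)       # odds ratios with 95% HPD intervals
diagnose(fit)   # ESS, split R-hat, acceptance, flags
```

The univariate bed-size model (`univariate_fit()`) applies the same machinery,
minus random effects, to the 2×2 sufficient statistics; on the bundled counts
its posterior-mean odds ratio reproduces the published 4.06.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces a claims table whose *statistical* structure
matches what the analysis assumes, at the published cohort dimensions
(defaults: 69,252 surgeries, 9,922 institutions):

* **Clustering.** Surgeries are allocated to institutions by a multinomial over
  symmetric-Dirichlet weights; the concentration knob
  (`institution_size_dispersion = 0.3`) produces the heavy right skew of a few
  high-volume centers among thousands of small ones. Institution effects are
  i.i.d. $N(0, \sigma_0^2)$; the default $\sigma_0^2 = 0.5$ is a package choice
  (the source reports no estimate) giving odds-ratio-scale heterogeneity of
  roughly $e^{\pm 1.4}$ across the central 95% of institutions — plausible for
  practice-style variation.
* **Covariates.** Binary patient flags drawn independently at published
  marginal frequencies (57.0% female, 69.0% outpatient, 2.5% antiplatelet
  use, ...); the ophthalmologic-procedure share (40%) is a package assumption,
  as only its effect size, not its prevalence, was published. Institution
  covariates: bed class (40.6% at ≥100 beds) and teaching status (7.8%).
  Covariates are independent by construction — only marginals were published —
  so the generator cannot reproduce real-world confounding structure beyond the
  institution effect itself. Effect sizes default to the published
  multivariable log odds ratios.
* **Outcome and dates.** A latent ordering event occurs with probability
  $\mathrm{logistic}(\beta_0 + x'\beta + c_i)$. The intercept is calibrated
  deterministically (exact enumeration over covariate patterns, fixed
  quadrature over $c$) so the marginal prevalence hits the published 59.0%.
  Positive surgeries receive per-test order dates uniformly within the 60-day
  window (per-test inclusion probabilities derived from the published per-test
  prevalences, CBC forced if none is drawn); negatives may carry historical
  dates strictly outside it. The window rule is **closed at both ends**
  ([0, 60] days; same-day orders count) — the source says only "within 60
  days", and inclusiveness was chosen and documented.
* **Planted exclusions.** About a fifth of raw rows violate an inclusion rule
  (age outside 20–64, under 12 months' enrollment, inpatient with an
  additional/emergency procedure), mirroring the published exclusion fraction,
  so the filter has real work to do and reports a flow ledger.

A green test on synthetic data establishes that the *machinery* is correct
(filters, tabulation, conjugate algebra, sampler calibration, parameter
recovery). It does not validate the published multivariable odds ratios, which
would require the proprietary source data; those are explicitly out of scope,
and only the 2×2-derived results are treated as reproducible targets.

## Degenerate inputs and numerical policy

* `two_by_two()` demands integer counts with $0 \le z \le n$; empty tables are
  a typed error for rates, and `z = n = 0` legitimately returns the prior.
* Beta shapes, probabilities, tolerances and MCMC settings are validated with
  errors naming the offending field.
* `sigma0_sq <= 0` inside the posterior is $-\infty$ (rejected region), not an
  exception; a non-finite log posterior at initialization is an error
  suggesting the default start.
* Constant (degenerate) chains are flagged, not errors: autocorrelation is
  `NA` beyond lag 0, ESS is 0 with a warning, HPD width is 0.
* Ties in the operation-count quartiles share a quartile (nearest-rank
  quantiles on institution-level counts).

## Known limitations

* The exact series for $\theta$ requires an integer shape at large magnitudes;
  for non-integer large shapes the package deliberately refuses rather than
  silently losing precision, and quadrature is the supported route.
* Random-walk MH mixes slowly for institution-level effects (high lag-1
  autocorrelation is expected and flagged); HMC/Gibbs alternatives are out of
  scope by design.
* The generator's independence assumptions (covariates, and the four test
  types conditional on the latent ordering event) are the weakest link to real
  claims data; the true inter-test correlation is not identifiable from
  published marginals and is exposed as configuration instead
  (`test_inclusion_probs`).
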