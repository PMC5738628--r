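Package: preopbayes
Title: Bayesian Analysis of Institutional Determinants of Preoperative Blood Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing preoperative blood-testing rates between
    institution groups in claims-based surgical cohorts. Implements conjugate
    beta-binomial updating, the exact Bayesian index theta = P(p1 < p2) for two
    binomial proportions via a generalized hypergeometric (3F2) series with
    quadrature and Monte Carlo cross-checks, equal-tailed credible intervals for
    the difference of two beta-distributed proportions by numerical convolution,
    and a two-level Bayesian logistic mixed model with institution random
    intercepts fitted by random-walk Metropolis-Hastings, summarized as odds
    ratios with highest-posterior-density intervals. A synthetic claims-cohort
    generator emulates the clustered structure of nationwide surgical claims
    data so the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
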