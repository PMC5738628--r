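# ggplot2 methods for the result objects; diagnostics plots mirror the
# numbers in diagnose() rather than carrying information of their own

#' Plot the posterior density of the rate difference
#'
#' Density of `D = p_large - p_small` with the equal-tailed credible region
#' shaded and the posterior mean marked.
#'
#' @param object A [rate_difference()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_difference <- function(object, ...) {
  dens <- object$density
  shade <- dplyr::filter(dens, .data$d >= object$lower, .data$d <= object$upper)
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$d, y = .data$density)) +
    ggplot2::geom_area(data = shade, fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = 2) +
    ggplot2::labs(
      x = "difference in testing rate (large - small)", y = "posterior density",
      title = sprintf("Difference %.3f [%g%% CrI %.3f to %.3f]",
                      object$estimate, 100 * object$level,
                      object$lower, object$upper)
    ) +
    ggplot2::theme_minimal()
}

#' Trace and density plots for a fitted model
#'
#' @param object A `preop_glmm` fit.
#' @param type `"trace"` (default) or `"density"`.
#' @param parameters Parameters to show; defaults to all fixed effects (plus
#'   `sigma0_sq` when present).
#' @param ... Unused.
#' @return A ggplot object, faceted by parameter.
#' @export
autoplot.preop_glmm <- function(object, type = c("trace", "density"),
                                parameters = NULL, ...) {
  type <- match.arg(type)
  params <- parameters %||% c(
    colnames(object$chains[[1]]$beta),
    if (object$settings$random_intercept) "sigma0_sq"
  )
  long <- purrr::map_dfr(seq_along(object$chains), function(k) {
    ch <- object$chains[[k]]
    purrr::map_dfr(params, function(pm) {
      x <- if (pm == "sigma0_sq") ch$sigma0_sq else ch$beta[, pm]
      tibble(chain = factor(k), parameter = pm,
             iteration = seq_along(x), value = x)
    })
  })
  p <- if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                       color = .data$chain)) +
      ggplot2::geom_line(linewidth = 0.2)
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value, color = .data$chain)) +
      ggplot2::geom_density()
  }
  p +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("Posterior %s", type))
}

#' Autocorrelation plot for a fitted model
#'
#' @param fit A `preop_glmm` fit.
#' @param max_lag Largest lag shown. Default 50.
#' @param parameters Parameters to show; defaults to the fixed effects.
#' @return A ggplot object.
#' @export
plot_acf <- function(fit, max_lag = 50, parameters = NULL) {
  stopifnot(inherits(fit, "preop_glmm"))
  params <- parameters %||% colnames(fit$chains[[1]]$beta)
  long <- purrr::map_dfr(params, function(pm) {
    x <- pooled_draws(fit, pm)
    dplyr::mutate(autocorrelation(x, min(max_lag, length(x) - 1L)),
                  parameter = pm)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lag, y = .data$autocorrelation)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter)) +
    ggplot2::theme_minimal()
}
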