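#' Plot distribution curves
#'
#' Convenience ggplot of the GMO-EE density, cdf, survival or hazard curve
#' over a grid; useful for exploring the hazard-shape repertoire (bathtub,
#' upside-down bathtub, monotone, constant).
#'
#' @param alpha,lambda,theta,beta GMO-EE parameters.
#' @param what One of `"density"`, `"cdf"`, `"survival"`, `"hazard"`.
#' @param from,to Grid range; `to` defaults to the 0.995 quantile.
#' @param n Grid size.
#' @return A ggplot object.
#' @export
plot_gmoee <- function(alpha, lambda, theta, beta,
                       what = c("density", "cdf", "survival", "hazard"),
                       from = NULL, to = NULL, n = 400) {
  what <- match.arg(what)
  to <- to %||% qgmoee(0.995, alpha, lambda, theta, beta)
  from <- from %||% (to / n)
  grid <- seq(from, to, length.out = n)
  y <- switch(what,
    density = dgmoee(grid, alpha, lambda, theta, beta),
    cdf = pgmoee(grid, alpha, lambda, theta, beta),
    survival = sgmoee(grid, alpha, lambda, theta, beta),
    hazard = hgmoee(grid, alpha, lambda, theta, beta))
  ggplot2::ggplot(tibble(x = grid, y = y),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x", y = what,
                  title = sprintf("GMO-EE(%.3g, %.3g, %.3g, %.3g)",
                                  alpha, lambda, theta, beta)) +
    ggplot2::theme_minimal()
}

#' Overlay a fitted cdf on the empirical cdf
#'
#' @param object A [gmoee_fit()] object.
#' @param ... Unused.
#' @return A ggplot object showing the empirical cdf of the data and the
#'   fitted model cdf.
#' @export
autoplot.gmoee_fit <- function(object, ...) {
  x <- sort(object$data)
  grid <- seq(min(x) * 0.5, max(x) * 1.05, length.out = 400)
  cdf <- fit_cdf_(object)
  df_emp <- tibble(x = x, ecdf = seq_along(x) / length(x))
  df_fit <- tibble(x = grid, G = cdf(grid))
  ggplot2::ggplot() +
    ggplot2::geom_step(data = df_emp,
                       ggplot2::aes(x = .data$x, y = .data$ecdf),
                       color = "grey40") +
    ggplot2::geom_line(data = df_fit,
                       ggplot2::aes(x = .data$x, y = .data$G),
                       color = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = "x", y = "cdf",
                  title = sprintf("%s fit (%s), n = %d",
                                  model_label_(object$model), object$method,
                                  object$nobs)) +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo bias and MSE trajectories
#'
#' @param object A `gmoee_sim` tibble from [run_sim_study()].
#' @param metric `"mean_bias"` or `"mse"`.
#' @param ... Unused.
#' @return A ggplot faceted by parameter, colored by estimator.
#' @export
autoplot.gmoee_sim <- function(object, metric = c("mean_bias", "mse"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n, y = .data[[metric]],
                               color = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$eta_index),
                        cols = ggplot2::vars(.data$parameter),
                        scales = "free_y") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::labs(x = "sample size", y = metric, color = "estimator") +
    ggplot2::theme_minimal()
}
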