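#' Goodness-of-fit statistics against a fitted continuous cdf
#'
#' Classical empirical-distribution-function statistics for a positive sample
#' against a candidate continuous cdf: the Kolmogorov-Smirnov sup-norm
#' \deqn{D = \max_i \max\{i/n - G(x_{(i)}),\; G(x_{(i)}) - (i-1)/n\},}
#' the Anderson-Darling statistic
#' \deqn{A^2 = -n - \frac1n \sum_i (2i-1) [\log G(x_{(i)}) +
#'   \log(1 - G(x_{(n+1-i)}))],}
#' and the Cramér-von Mises statistic
#' \deqn{W^2 = \frac{1}{12n} + \sum_i [G(x_{(i)}) - \frac{2i-1}{2n}]^2.}
#' Probability-integral values are clamped into `[1e-12, 1 - 1e-12]` before
#' taking logs (a clamp is reported via attribute `"clamped"`). All three
#' statistics are invariant to the input ordering.
#'
#' @param x Positive sample (vector or data frame).
#' @param cdf A vectorized cdf evaluator, e.g. `function(q) pgmoee(q, ...)`.
#' @return A scalar statistic.
#' @examples
#' ks_stat(rexp(50, 2), function(q) pexp(q, 2))
#' @name gof-statistics
NULL

#' @rdname gof-statistics
#' @export
ks_stat <- function(x, cdf) {
  x <- sample_values(x)
  n <- length(x)
  u <- cdf(sort(x))
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

#' @rdname gof-statistics
#' @export
ad_stat <- function(x, cdf) {
  x <- sample_values(x)
  n <- length(x)
  u <- cdf(sort(x))
  clamped <- any(u < 1e-12 | u > 1 - 1e-12)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(u) + log1p(-rev(u))))
  structure(a2, clamped = clamped)
}

#' @rdname gof-statistics
#' @export
cvm_stat <- function(x, cdf) {
  x <- sample_values(x)
  n <- length(x)
  u <- cdf(sort(x))
  i <- seq_len(n)
  1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
}

# ---- approximate p-values --------------------------------------------------
# All three use the classical simple-hypothesis asymptotics; with estimated
# parameters they are conservative and are documented as approximate.

# Kolmogorov asymptotic tail: P(sqrt(n) D > z) = 2 sum (-1)^{k-1} exp(-2k^2 z^2)
ks_pvalue_ <- function(d, n) {
  z <- sqrt(n) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * z^2))
  min(max(p, 0), 1)
}

# Anderson-Darling asymptotic p for the case-0 A^2 statistic:
# Marsaglia & Marsaglia's two-piece approximation of the limiting cdf
ad_pvalue_ <- function(a2) {
  z <- as.numeric(a2)
  if (z <= 0) return(1)
  cdf <- if (z < 2) {
    z^(-0.5) * exp(-1.2337141 / z) *
      (2.00012 + (0.247105 - (0.0649821 - (0.0347962 -
        (0.0116720 - 0.00168691 * z) * z) * z) * z) * z)
  } else {
    exp(-exp(1.0776 - (2.30695 - (0.43424 - (0.082433 -
      (0.008056 - 0.0003146 * z) * z) * z) * z) * z))
  }
  min(max(1 - cdf, 0), 1)
}

# Cramer-von Mises limiting distribution: Bessel-K series for the body
# (Anderson-Darling 1952), leading-eigenvalue asymptotics for the tail
# (smallest weight 1/pi^2, correction prod_{j>=2}(1 - 1/j^2)^{-1/2} = sqrt 2)
cvm_pvalue_ <- function(w2) {
  x <- as.numeric(w2)
  if (x <= 0) return(1)
  if (x > 0.4) {
    p <- 2 * sqrt(2) * stats::pnorm(pi * sqrt(x), lower.tail = FALSE)
    return(min(max(p, 0), 1))
  }
  j <- 0:9
  a <- exp(lgamma(j + 0.5) - lgamma(0.5) - lgamma(j + 1))
  s <- (4 * j + 1)^2 / (16 * x)
  terms <- (-1)^j * a * sqrt(4 * j + 1) * exp(-s) * besselK(s, 0.25)
  terms[!is.finite(terms)] <- 0
  cdf <- sum(terms) / (pi * sqrt(x))
  min(max(1 - cdf, 0), 1)
}

#' Goodness-of-fit report for a fitted model
#'
#' Assembles the model-comparison row used throughout the applications:
#' \eqn{-2\log L}, AIC (\eqn{-2\log L + 2k} with `k` free parameters), the
#' Anderson-Darling, Cramér-von Mises and Kolmogorov-Smirnov statistics of
#' the fitted cdf, and approximate p-values (simple-hypothesis asymptotics;
#' see [gof-statistics]).
#'
#' @param fit A [gmoee_fit()] / baseline fit object.
#' @param model_name Optional display name; defaults to the fit's model.
#' @return A one-row tibble with columns `model`, `k`, `neg2loglik`, `aic`,
#'   `ad`, `cvm`, `ks`, `p_ad`, `p_cvm`, `p_ks`.
#' @export
gof_report <- function(fit, model_name = NULL) {
  stopifnot(inherits(fit, "gmoee_fit"))
  x <- fit$data
  cdf <- fit_cdf_(fit)
  k <- length(fit$estimate) - length(fit$fixed)
  n2l <- -2 * fit$loglik
  ad <- as.numeric(ad_stat(x, cdf))
  cvm <- cvm_stat(x, cdf)
  ks <- ks_stat(x, cdf)
  tibble(
    model = model_name %||% model_label_(fit$model),
    k = k,
    neg2loglik = n2l,
    aic = n2l + 2 * k,
    ad = ad, cvm = cvm, ks = ks,
    p_ad = ad_pvalue_(ad),
    p_cvm = cvm_pvalue_(cvm),
    p_ks = ks_pvalue_(ks, length(x))
  )
}

#' Model-comparison table for a sample
#'
#' Fits the GMO-EE distribution (maximum likelihood) together with the EE,
#' Weibull and exponential baselines and stacks their [gof_report()] rows,
#' mirroring the selection-criteria tables of the real-data applications.
#'
#' @param x Positive sample (vector or data frame).
#' @param starts,seed Multistart settings passed to [gmoee_fit()].
#' @param models Character subset of
#'   `c("gmoee", "ee", "weibull", "exponential")`.
#' @return A tibble with one row per model, carrying the fitted objects in a
#'   list column `fit`.
#' @examples
#' \donttest{
#' gof_table(gmoee_data("covid_recovery_m60"), starts = 10, seed = 1)
#' }
#' @export
gof_table <- function(x, starts = 25, seed = NULL,
                      models = c("gmoee", "ee", "weibull", "exponential")) {
  x <- sample_values(x)
  models <- match.arg(models, several.ok = TRUE)
  fits <- purrr::map(models, function(m) {
    switch(m,
      gmoee = gmoee_fit(x, method = "mle", starts = starts, seed = seed),
      ee = fit_ee(x),
      weibull = fit_weibull(x),
      exponential = fit_exponential(x))
  })
  out <- purrr::map_dfr(fits, gof_report)
  out$fit <- fits
  out
}

#' Write a model-comparison table to disk
#'
#' @param table A tibble from [gof_table()] (the `fit` column is dropped).
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @param digits Decimal places for the statistics (default 4, matching the
#'   display convention of the comparison tables).
#' @return `path`, invisibly.
#' @export
write_gof_table <- function(table, path, format = c("csv", "tsv"), digits = 4) {
  format <- match.arg(format)
  tbl <- dplyr::select(table, -dplyr::any_of("fit"))
  num <- vapply(tbl, is.numeric, logical(1)) & names(tbl) != "k"
  tbl[num] <- lapply(tbl[num], function(v) round(v, digits))
  utils::write.table(tbl, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
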