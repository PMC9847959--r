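#' Fit the GMO-EE distribution to a positive sample
#'
#' Five frequentist estimators of the parameter vector
#' `(alpha, lambda, theta, beta)`:
#' \describe{
#'   \item{`"mle"`}{maximum likelihood;}
#'   \item{`"lse"`}{ordinary least squares against the plotting positions
#'     `i/(n+1)`, minimizing \eqn{\sum_i [G(x_{(i)}) - i/(n+1)]^2};}
#'   \item{`"wlse"`}{weighted least squares with weights
#'     \eqn{w_i = (n+1)^2 (n+2) / (i (n-i+1))}, the reciprocal of the
#'     variance of the empirical cdf at the i-th order statistic;}
#'   \item{`"ade"`}{minimum Anderson-Darling distance, minimizing
#'     \eqn{-n - \frac1n \sum_i (2i-1)[\log G(x_{(i)}) +
#'     \log(1 - G(x_{(n+1-i)}))]};}
#'   \item{`"cvme"`}{minimum Cramér-von Mises distance, minimizing
#'     \eqn{\frac{1}{12n} + \sum_i [G(x_{(i)}) - \frac{2i-1}{2n}]^2}.}
#' }
#' All five share one optimizer harness: the box constraints are removed by
#' optimizing over `(logit(alpha), logit(lambda), log(theta), log(beta))`,
#' each start is run through Nelder-Mead and then a BFGS polish, and the best
#' of `starts` Latin-hypercube starts (plus one moment-based heuristic start)
#' is returned. Standard errors (maximum likelihood only) come from the
#' inverse of the numerical Hessian of the negative log-likelihood at the
#' optimum (observed information).
#'
#' @param x Numeric vector of strictly positive observations, or a data frame
#'   whose first numeric column holds them (so fits chain off
#'   [gmoee_data()] with the pipe).
#' @param method One of `"mle"`, `"lse"`, `"wlse"`, `"ade"`, `"cvme"`.
#' @param starts Number of Latin-hypercube multistarts (default 25).
#' @param seed Optional integer seed for the start draws; the caller's RNG
#'   state is restored afterwards.
#' @param fixed Optional named numeric vector of parameters to hold fixed,
#'   e.g. `c(alpha = 1, lambda = 1, beta = 1)` fits the exponential submodel.
#' @param weights `"variance"` (default, reciprocal empirical-cdf variance) or
#'   `"printed"` for the `(n+1)^3` weight variant.
#' @param ad_variant `"standard"` (default) or `"literal"`, which applies both
#'   Anderson-Darling logs to the same order statistic.
#' @param se Compute standard errors for the maximum-likelihood fit (default
#'   `TRUE`; Monte Carlo loops switch this off since only point estimates are
#'   summarized).
#' @param control List of optimizer settings: `maxit` (default 2000),
#'   `reltol` (default 1e-10).
#' @return An object of class `gmoee_fit`: a list with elements `model`,
#'   `method`, `estimate`, `se`, `loglik`, `objective`, `converged`,
#'   `n_starts`, `nobs`, `data` and `trace` (a tibble with one row per
#'   start). Use [tidy()] for a parameter table, [glance()] for a one-row
#'   model summary, and [autoplot()] for a cdf overlay.
#' @examples
#' x <- gmoee_data("wheaton_flood")
#' fit <- gmoee_fit(x, method = "mle", starts = 5, seed = 1)
#' tidy(fit)
#' @export
gmoee_fit <- function(x, method = c("mle", "lse", "wlse", "ade", "cvme"),
                      starts = 25, seed = NULL, fixed = NULL,
                      weights = c("variance", "printed"),
                      ad_variant = c("standard", "literal"),
                      se = TRUE, control = list()) {
  x <- sample_values(x)
  method <- match.arg(method)
  weights <- match.arg(weights)
  ad_variant <- match.arg(ad_variant)
  if (length(x) < 5) abort("at least 5 observations are required.")
  ctrl <- modifyList(list(maxit = 2000L, reltol = 1e-10), control)

  obj <- build_objective_(x, method, weights, ad_variant)
  grad <- if (method == "mle") {
    function(eta) -gmoee_score(x, eta$alpha, eta$lambda, eta$theta, eta$beta)
  } else {
    NULL
  }
  res <- multistart_optim_(obj, grad, x, starts = starts, seed = seed,
                           fixed = fixed, ctrl = ctrl)

  est <- res$estimate
  ll <- gmoee_loglik(x, est[["alpha"]], est[["lambda"]], est[["theta"]],
                     est[["beta"]])
  ses <- setNames(rep(NA_real_, 4), param_names)
  if (method == "mle" && isTRUE(se)) {
    ses <- mle_se_(x, est, fixed)
  }
  structure(list(
    model = "gmoee", method = toupper(method), estimate = est, se = ses,
    loglik = ll,
    objective = if (method == "mle") ll else res$value,
    converged = res$converged, n_starts = res$n_starts,
    nobs = length(x), data = x, fixed = fixed, trace = res$trace
  ), class = "gmoee_fit")
}

# objective (to be minimized) over a full parameter list
build_objective_ <- function(x, method, weights, ad_variant) {
  n <- length(x)
  xs <- sort(x)
  i <- seq_len(n)
  pp <- i / (n + 1)
  eps <- 1e-12
  w <- if (weights == "variance") {
    (n + 1)^2 * (n + 2) / (i * (n - i + 1))
  } else {
    (n + 1)^2 * (n + 1) / (i * (n - i + 1))
  }
  switch(method,
    mle = function(eta) {
      -gmoee_loglik(x, eta$alpha, eta$lambda, eta$theta, eta$beta)
    },
    lse = function(eta) {
      G <- pgmoee(xs, eta$alpha, eta$lambda, eta$theta, eta$beta)
      sum((G - pp)^2)
    },
    wlse = function(eta) {
      G <- pgmoee(xs, eta$alpha, eta$lambda, eta$theta, eta$beta)
      sum(w * (G - pp)^2)
    },
    ade = function(eta) {
      G <- pgmoee(xs, eta$alpha, eta$lambda, eta$theta, eta$beta)
      G <- pmin(pmax(G, eps), 1 - eps)
      Gi2 <- if (ad_variant == "standard") rev(G) else G
      -n - mean((2 * i - 1) * (log(G) + log1p(-Gi2)))
    },
    cvme = function(eta) {
      G <- pgmoee(xs, eta$alpha, eta$lambda, eta$theta, eta$beta)
      1 / (12 * n) + sum((G - (2 * i - 1) / (2 * n))^2)
    }
  )
}

# ---- optimizer harness -----------------------------------------------------
# unconstrained coordinates: logit for alpha/lambda, log for theta/beta
u_to_val_ <- function(u, nm) if (nm %in% c("alpha", "lambda")) plogis(u) else exp(u)
val_to_u_ <- function(v, nm) if (nm %in% c("alpha", "lambda")) qlogis(v) else log(v)
# d(value)/d(u), for chain-rule gradients
u_jac_ <- function(v, nm) if (nm %in% c("alpha", "lambda")) v * (1 - v) else v

multistart_optim_ <- function(obj, grad, x, starts, seed, fixed, ctrl) {
  free <- param_names
  fixed_vals <- numeric(0)
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% param_names)) {
      abort("`fixed` must be a named vector using alpha/lambda/theta/beta.")
    }
    fixed_vals <- fixed
    free <- setdiff(param_names, names(fixed))
  }
  if (!length(free)) abort("at least one parameter must be free.")

  to_eta <- function(u) {
    eta <- as.list(fixed_vals)
    for (k in seq_along(free)) eta[[free[k]]] <- u_to_val_(u[k], free[k])
    eta[param_names]
  }
  fn_u <- function(u) {
    eta <- to_eta(u)
    v <- tryCatch(obj(eta), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  gr_u <- if (!is.null(grad)) {
    function(u) {
      eta <- to_eta(u)
      g <- tryCatch(grad(eta), error = function(e) rep(NA_real_, 4))
      if (anyNA(g) || any(!is.finite(g))) {
        return(numDeriv_grad_(fn_u, u))
      }
      vapply(seq_along(free), function(k) {
        g[[free[k]]] * u_jac_(eta[[free[k]]], free[k])
      }, numeric(1))
    }
  } else {
    NULL
  }

  start_mat <- start_points_(x, starts, seed)[, free, drop = FALSE]
  # a deterministic moment-flavoured start in addition to the LHS draws
  heur <- c(alpha = 0.5, lambda = 0.5, theta = 1 / mean(x), beta = 1)
  start_mat <- rbind(start_mat, heur[free])

  best <- NULL
  trace <- vector("list", nrow(start_mat))
  for (s in seq_len(nrow(start_mat))) {
    u0 <- vapply(free, function(nm) val_to_u_(start_mat[s, nm], nm), numeric(1))
    fit <- tryCatch({
      # Nelder-Mead is unreliable (and noisy) in one dimension
      stage1 <- if (length(u0) > 1) "Nelder-Mead" else "BFGS"
      nm_fit <- optim(u0, fn_u, method = stage1,
                      control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
      bf <- tryCatch(
        optim(nm_fit$par, fn_u, gr = gr_u, method = "BFGS",
              control = list(maxit = ctrl$maxit, reltol = ctrl$reltol)),
        error = function(e) nm_fit)
      if (is.finite(bf$value) && bf$value <= nm_fit$value) bf else nm_fit
    }, error = function(e) NULL)
    if (is.null(fit)) {
      trace[[s]] <- tibble(start = s, value = NA_real_, convergence = NA_integer_)
      next
    }
    trace[[s]] <- tibble(start = s, value = fit$value,
                         convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("all optimizer starts failed.")
  eta <- to_eta(best$par)
  list(
    estimate = setNames(unlist(eta), param_names),
    value = best$value,
    converged = is.finite(best$value) && best$value < 1e10 &&
      best$convergence == 0L,
    n_starts = nrow(start_mat),
    trace = dplyr::bind_rows(trace)
  )
}

# Latin-hypercube starts over a data-scaled box:
# alpha, lambda in [0.05, 0.99]; theta log-uniform in [0.1, 10]/mean(x);
# beta log-uniform in [0.2, 20]
start_points_ <- function(x, starts, seed) {
  m <- with_seed(seed, lhs::randomLHS(max(1L, as.integer(starts)), 4L))
  mx <- mean(x)
  cbind(
    alpha = 0.05 + m[, 1] * 0.94,
    lambda = 0.05 + m[, 2] * 0.94,
    theta = exp(log(0.1 / mx) + m[, 3] * log(100)),
    beta = exp(log(0.2) + m[, 4] * log(100))
  )
}

numDeriv_grad_ <- function(f, u, h = 1e-6) {
  vapply(seq_along(u), function(k) {
    e <- numeric(length(u)); e[k] <- h
    (f(u + e) - f(u - e)) / (2 * h)
  }, numeric(1))
}

# observed-information standard errors at the MLE (raw parameter scale)
mle_se_ <- function(x, est, fixed) {
  se <- setNames(rep(NA_real_, 4), param_names)
  free <- setdiff(param_names, names(fixed))
  negll <- function(par) {
    eta <- as.list(est)
    eta[free] <- par
    v <- tryCatch(
      -gmoee_loglik(x, eta$alpha, eta$lambda, eta$theta, eta$beta),
      error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  H <- tryCatch(optimHess(unname(est[free]), negll), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(V) || any(diag(V) <= 0)) {
    warn("observed information not positive definite; standard errors set to NA")
    return(se)
  }
  se[free] <- sqrt(diag(V))
  se
}

#' @export
print.gmoee_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (%s), n = %d\n", model_label_(x$model), x$method, x$nobs))
  est <- formatC(x$estimate, digits = digits, format = "f")
  se <- ifelse(is.na(x$se), "-",
               paste0("(", formatC(x$se, digits = digits, format = "f"), ")"))
  for (k in seq_along(x$estimate)) {
    cat(sprintf("  %-7s %s %s\n", names(x$estimate)[k], est[k], se[k]))
  }
  if (!is.na(x$loglik)) {
    cat(sprintf("  logLik %.4f  (-2log = %.2f)\n", x$loglik, -2 * x$loglik))
  }
  if (!isTRUE(x$converged)) cat("  ! optimizer did not report convergence\n")
  invisible(x)
}

model_label_ <- function(model) {
  switch(model, gmoee = "GMO-EE", ee = "EE", weibull = "Weibull",
         exponential = "Exponential", model)
}

#' Broom-style summaries of fitted models
#'
#' @param x,object A [gmoee_fit()] or baseline fit object.
#' @param ... Unused.
#' @return `tidy()` gives one row per parameter (term, estimate, std.error);
#'   `glance()` gives a one-row model summary with `logLik`, `AIC`, `nobs`.
#' @export
tidy.gmoee_fit <- function(x, ...) {
  tibble(term = names(x$estimate),
         estimate = unname(x$estimate),
         std.error = unname(x$se))
}

#' @rdname tidy.gmoee_fit
#' @export
glance.gmoee_fit <- function(x, ...) {
  k <- length(x$estimate) - length(x$fixed)
  tibble(model = x$model, method = x$method, nobs = x$nobs,
         logLik = x$loglik, AIC = -2 * x$loglik + 2 * k,
         objective = x$objective, converged = x$converged,
         n_starts = x$n_starts)
}

# cdf evaluator for any fitted model in the package
fit_cdf_ <- function(fit) {
  est <- fit$estimate
  switch(fit$model,
    gmoee = function(q) pgmoee(q, est[["alpha"]], est[["lambda"]],
                               est[["theta"]], est[["beta"]]),
    ee = function(q) pee(q, est[["theta"]], est[["beta"]]),
    weibull = function(q) pweibull(q, est[["shape"]], est[["scale"]]),
    exponential = function(q) stats::pexp(q, est[["rate"]]),
    abort(sprintf("unknown model '%s'", fit$model))
  )
}
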