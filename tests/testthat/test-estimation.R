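test_that("log-likelihood equals the direct expression and its closed forms", {
  set.seed(1)
  x <- rgmoee(40, 0.4, 0.8, 1, 0.5)
  e <- list(alpha = 0.3, lambda = 0.9, theta = 1.2, beta = 0.7)
  # independent transcription of the log-likelihood as a sum of four blocks
  A <- 1 - exp(-e$theta * x)
  F <- A^e$beta
  direct <- sum(log((1 - e$alpha) * (1 - e$lambda) * F^2 +
                      2 * e$alpha * (1 - e$lambda) * F + e$alpha * e$lambda)) +
    length(x) * log(e$theta * e$beta) - e$theta * sum(x) +
    (e$beta - 1) * sum(log(A)) -
    2 * sum(log(e$alpha + (1 - e$alpha) * F))
  expect_equal(gmoee_loglik(x, e$alpha, e$lambda, e$theta, e$beta), direct,
               tolerance = 1e-10)
  # exponential submodel closed form
  expect_equal(gmoee_loglik(x, 1, 1, 2, 1), length(x) * log(2) - 2 * sum(x),
               tolerance = 1e-10)
})

test_that("analytic score matches numerical gradients across the box", {
  set.seed(2)
  x <- rgmoee(60, 0.5, 0.7, 3, 0.9)
  etas <- random_etas(15, seed = 4)
  for (k in seq_len(nrow(etas))) {
    e <- as.numeric(etas[k, ])
    g <- gmoee_score(x, e[1], e[2], e[3], e[4])
    gn <- num_grad(function(p) gmoee_loglik(x, p[1], p[2], p[3], p[4]), e)
    expect_equal(unname(g), gn, tolerance = 1e-5)
  }
  # exponential submodel: theta-component is n/theta - sum(x)
  g <- gmoee_score(x, 1, 1, 2, 1)
  expect_equal(unname(g["theta"]), length(x) / 2 - sum(x), tolerance = 1e-8)
})

test_that("score vanishes at an interior maximum-likelihood optimum", {
  set.seed(3)
  x <- rgmoee(300, 0.5, 0.7, 1, 0.9)
  fit <- gmoee_fit(x, "mle", starts = 8, seed = 1, se = FALSE)
  est <- fit$estimate
  # only components away from the boundary are first-order conditions
  free <- est[c("alpha", "lambda")] < 0.999
  g <- gmoee_score(x, est[1], est[2], est[3], est[4])
  expect_lt(max(abs(g[c(free, TRUE, TRUE)])), 1e-4 * length(x))
})

test_that("constrained submodel fit recovers the closed-form exponential MLE", {
  set.seed(4)
  x <- rexp(200, 2.5)
  fit <- gmoee_fit(x, "mle", starts = 3, seed = 1,
                   fixed = c(alpha = 1, lambda = 1, beta = 1))
  expect_equal(unname(fit$estimate["theta"]), 1 / mean(x), tolerance = 1e-6)
  expect_equal(fit$estimate[["alpha"]], 1)
})

test_that("distance estimators recover exact plotting-position data", {
  e <- c(0.4, 0.8, 1, 0.5)
  n <- 80
  x_ls <- qgmoee((1:n) / (n + 1), e[1], e[2], e[3], e[4])
  obj_ls <- gmoee:::build_objective_(x_ls, "lse", "variance", "standard")
  expect_lt(obj_ls(as_obj <- list(alpha = e[1], lambda = e[2],
                                  theta = e[3], beta = e[4])), 1e-20)
  fit <- gmoee_fit(x_ls, "lse", starts = 10, seed = 2)
  expect_lt(fit$objective, 1e-8)
  # CvM attains its floor 1/(12n) on (2i-1)/(2n) quantile data
  x_cv <- qgmoee((2 * (1:n) - 1) / (2 * n), e[1], e[2], e[3], e[4])
  obj_cv <- gmoee:::build_objective_(x_cv, "cvme", "variance", "standard")
  expect_equal(obj_cv(as_obj), 1 / (12 * n), tolerance = 1e-12)
})

test_that("every estimator beats random feasible parameter points", {
  set.seed(5)
  x <- rgmoee(150, 0.5, 0.7, 2, 0.9)
  cand <- random_etas(50, seed = 6)
  for (m in c("mle", "lse", "wlse", "ade", "cvme")) {
    fit <- gmoee_fit(x, m, starts = 8, seed = 3, se = FALSE)
    obj <- gmoee:::build_objective_(x, m, "variance", "standard")
    at_opt <- obj(as.list(fit$estimate))
    audit <- vapply(seq_len(nrow(cand)), function(k) {
      obj(as.list(cand[k, ]))
    }, numeric(1))
    expect_lt(at_opt, min(audit) + 1e-10)
  }
})

test_that("maximum likelihood recovers the truth from a large sample", {
  x <- gmoee_sample(5000, 0.4, 0.8, 1, 0.5, seed = 12)
  fit <- gmoee_fit(x, "mle", starts = 10, seed = 2)
  truth <- c(alpha = 0.4, lambda = 0.8, theta = 1, beta = 0.5)
  ok <- !is.na(fit$se)
  expect_true(all(abs(fit$estimate[ok] - truth[ok]) <= 3 * fit$se[ok]))
  # likelihood at the fit dominates the likelihood at the other estimators
  for (m in c("lse", "wlse", "ade", "cvme")) {
    alt <- gmoee_fit(x, m, starts = 5, seed = 2)$estimate
    expect_gte(fit$loglik + 1e-6,
               gmoee_loglik(x, alt[1], alt[2], alt[3], alt[4]))
  }
})

test_that("transformed-coordinate optimum matches raw clipped optimization", {
  x <- gmoee_data("covid_recovery_m60")$value
  fit <- fixture_mle("covid_recovery_m60")
  # raw-coordinate box-constrained optimizer from the same start box
  negll_raw <- function(p) {
    v <- -gmoee_loglik(x, p[1], p[2], p[3], p[4])
    if (!is.finite(v)) 1e10 else v
  }
  starts <- rbind(gmoee:::start_points_(x, 10, seed = 1),
                  c(0.5, 0.5, 1 / mean(x), 1))
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    raw <- tryCatch(
      optim(starts[s, ], negll_raw, method = "L-BFGS-B",
            lower = c(1e-6, 1e-6, 1e-9, 1e-6), upper = c(1, 1, Inf, Inf),
            control = list(maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(raw)) best <- min(best, raw$value)
  }
  expect_lt(abs(-best - fit$loglik), 1e-4 * abs(fit$loglik))
})

test_that("independent mledist cross-check cannot improve on the fitted optimum", {
  x <- gmoee_data("wheaton_flood")$value
  fit <- fixture_mle("wheaton_flood")
  alt <- suppressWarnings(fitdistrplus::mledist(
    x, "gmoee",
    start = list(alpha = 0.5, lambda = 0.5, theta = 1 / mean(x), beta = 1),
    lower = c(1e-4, 1e-4, 1e-6, 1e-3), upper = c(1, 1, 10, 50)))
  expect_gte(fit$loglik + 1e-4, alt$loglik)
})

test_that("fit accepts data frames and validates input", {
  df <- gmoee_data("covid_recovery_m60")
  fit <- gmoee_fit(df, "mle", starts = 2, seed = 1, se = FALSE)
  expect_s3_class(fit, "gmoee_fit")
  expect_equal(fit$nobs, 50)
  expect_error(gmoee_fit(c(1, 2, -3, 4, 5)), "positive")
  expect_error(gmoee_fit(c(1, 2)), "at least 5")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("alpha", "lambda", "theta", "beta"))
  gl <- glance(fit)
  expect_equal(gl$AIC, -2 * gl$logLik + 8, tolerance = 1e-10)
  expect_output(print(fit), "GMO-EE fit \\(MLE\\)")
})
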