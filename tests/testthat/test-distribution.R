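test_that("submodel reductions recover EE and exponential pointwise", {
  x <- c(0.01, 0.1, 0.5, 1, 2, 5, 10)
  # alpha = lambda = 1 -> EE(theta, beta)
  expect_equal(pgmoee(x, 1, 1, 1.3, 2.2), pee(x, 1.3, 2.2), tolerance = 1e-12)
  expect_equal(dgmoee(x, 1, 1, 1.3, 2.2), dee(x, 1.3, 2.2), tolerance = 1e-12)
  # additionally beta = 1 -> exponential(theta)
  expect_equal(pgmoee(x, 1, 1, 2, 1), pexp(x, 2), tolerance = 1e-12)
  expect_equal(dgmoee(x, 1, 1, 2, 1), dexp(x, 2), tolerance = 1e-12)
  expect_equal(qgmoee(0.5, 1, 1, 1, 1), log(2), tolerance = 1e-12)
  # exponential memorylessness: constant hazard = theta
  expect_equal(hgmoee(x, 1, 1, 2, 1), rep(2, length(x)), tolerance = 1e-10)
})

test_that("EE cdf matches quadrature of its density", {
  # (theta = 1, beta = 2): integrate the density over [0, 1]
  oracle <- integrate(function(t) dee(t, 1, 2), 0, 1, rel.tol = 1e-12)$value
  expect_equal(pee(1, 1, 2), oracle, tolerance = 1e-10)
  expect_equal(pee(1, 1, 2), (1 - exp(-1))^2, tolerance = 1e-12)
  expect_equal(pee(0, 3, 2), 0)
  expect_equal(pee(log(2), 1, 1), 0.5, tolerance = 1e-12)
})

test_that("density integrates to one and matches the cdf across the box", {
  etas <- random_etas(200, seed = 42)
  for (k in seq_len(nrow(etas))) {
    e <- etas[k, ]
    total <- integrate(function(t) dgmoee(t, e$alpha, e$lambda, e$theta, e$beta),
                       0, Inf, rel.tol = 1e-9, stop.on.error = FALSE)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # cdf equals quadrature of the pdf on an x-grid for a handful of etas
  for (k in 1:5) {
    e <- etas[k, ]
    for (x in c(0.3, 1, 2.5)) {
      num <- integrate(function(t) dgmoee(t, e$alpha, e$lambda, e$theta, e$beta),
                       0, x, rel.tol = 1e-12)$value
      expect_equal(pgmoee(x, e$alpha, e$lambda, e$theta, e$beta), num,
                   tolerance = 1e-8)
    }
  }
})

test_that("pdf matches a finite difference of the cdf at fitted-scale parameters", {
  # air-conditioning fit scale: small theta, moderate beta
  e <- list(alpha = 0.1744, lambda = 0.7161, theta = 0.008, beta = 1.412)
  h <- 1e-4
  fd <- (pgmoee(50 + h, e$alpha, e$lambda, e$theta, e$beta) -
           pgmoee(50 - h, e$alpha, e$lambda, e$theta, e$beta)) / (2 * h)
  expect_equal(dgmoee(50, e$alpha, e$lambda, e$theta, e$beta), fd,
               tolerance = 1e-6)
})

test_that("survival and hazard satisfy their defining identities", {
  etas <- random_etas(20, seed = 7)
  xg <- exp(seq(log(0.05), log(20), length.out = 40))
  for (k in seq_len(nrow(etas))) {
    e <- etas[k, ]
    s <- sgmoee(xg, e$alpha, e$lambda, e$theta, e$beta)
    expect_equal(s, 1 - pgmoee(xg, e$alpha, e$lambda, e$theta, e$beta),
                 tolerance = 1e-10)
    ok <- s > 1e-12
    h <- hgmoee(xg[ok], e$alpha, e$lambda, e$theta, e$beta)
    expect_equal(h, dgmoee(xg[ok], e$alpha, e$lambda, e$theta, e$beta) / s[ok],
                 tolerance = 1e-10)
  }
  expect_equal(sgmoee(0, 0.4, 0.8, 1, 0.5), 1)
})

test_that("cdf is monotone and proper for every valid parameter vector", {
  etas <- random_etas(30, seed = 11)
  xg <- c(0, exp(seq(log(1e-3), log(50), length.out = 200)))
  for (k in seq_len(nrow(etas))) {
    e <- etas[k, ]
    G <- pgmoee(xg, e$alpha, e$lambda, e$theta, e$beta)
    expect_true(all(diff(G) >= -1e-14))
    expect_equal(G[1], 0)
    expect_gt(pgmoee(1e4 / e$theta, e$alpha, e$lambda, e$theta, e$beta), 1 - 1e-9)
  }
})

test_that("closed-form quantile round-trips through the cdf", {
  etas <- random_etas(100, seed = 3)
  p <- seq(0.01, 0.99, by = 0.01)
  for (k in seq_len(nrow(etas))) {
    e <- etas[k, ]
    x <- qgmoee(p, e$alpha, e$lambda, e$theta, e$beta)
    expect_true(all(diff(x) > 0))
    expect_lt(max(abs(pgmoee(x, e$alpha, e$lambda, e$theta, e$beta) - p)), 1e-9)
  }
  # boundaries
  expect_equal(qgmoee(0, 0.4, 0.8, 1, 0.5), 0)
  expect_lt(qgmoee(1e-10, 0.4, 0.8, 1, 0.5), 1e-4)
  expect_equal(qgmoee(1, 0.4, 0.8, 1, 0.5), Inf)
})

test_that("quantile agrees with independent root finding", {
  e <- list(alpha = 0.3, lambda = 0.6, theta = 2, beta = 0.8)
  for (p in c(0.05, 0.3, 0.5, 0.9)) {
    root <- uniroot(function(x) pgmoee(x, e$alpha, e$lambda, e$theta, e$beta) - p,
                    c(1e-12, 100), tol = 1e-12)$root
    expect_equal(qgmoee(p, e$alpha, e$lambda, e$theta, e$beta), root,
                 tolerance = 1e-7)
  }
})

test_that("density boundary behaviour at x = 0 follows the shape parameter", {
  expect_identical(dgmoee(0, 0.4, 0.8, 1, 0.5), Inf)
  expect_equal(dgmoee(0, 0.5, 0.8, 2, 1), 0.8 * 2 / 0.5, tolerance = 1e-12)
  expect_identical(dgmoee(0, 0.4, 0.8, 1, 2), 0)
  # never NaN near the origin
  expect_false(anyNA(dgmoee(c(0, 1e-300, 1e-12), 0.4, 0.8, 1, 0.5)))
})

test_that("parameter validation rejects out-of-box values", {
  expect_error(pgmoee(1, 0, 0.5, 1, 1), "alpha")
  expect_error(pgmoee(1, 1.2, 0.5, 1, 1), "alpha")
  expect_error(pgmoee(1, 0.5, 0, 1, 1), "lambda")
  expect_error(dgmoee(1, 0.5, 0.5, -1, 1), "theta")
  expect_error(qgmoee(0.5, 0.5, 0.5, 1, 0), "beta")
  expect_error(qgmoee(1.5, 0.5, 0.5, 1, 1))
})

test_that("random generation is reproducible and distributed as the cdf", {
  n <- 1e5
  s1 <- gmoee_sample(n, 0.4, 0.8, 1, 0.5, seed = 99)
  s2 <- gmoee_sample(n, 0.4, 0.8, 1, 0.5, seed = 99)
  expect_identical(s1$value, s2$value)
  expect_true(all(s1$value > 0))
  # one-sample K-S band at the 1% level
  d <- ks_stat(s1$value, function(q) pgmoee(q, 0.4, 0.8, 1, 0.5))
  expect_lt(d, 1.63 / sqrt(n))
  # exponential submodel mean
  m <- with_exp <- gmoee_sample(n, 1, 1, 1, 1, seed = 5)$value
  expect_lt(abs(mean(m) - 1), 3 / sqrt(n))
})
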