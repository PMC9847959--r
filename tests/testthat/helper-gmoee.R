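# draw valid parameter vectors spread over the box; deterministic per seed
random_etas <- function(n, seed = 1, alpha_min = 0.05) {
  set.seed(seed)
  data.frame(
    alpha = runif(n, alpha_min, 1),
    lambda = runif(n, 0.05, 1),
    theta = exp(runif(n, log(0.2), log(5))),
    beta = exp(runif(n, log(0.3), log(5)))
  )
}

# numeric central-difference gradient of f at x
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h * max(1, abs(x[k]))
    (f(x + e) - f(x - e)) / (2 * e[k])
  }, numeric(1))
}

# MLE fits of the four packaged datasets, computed once per test run
fixture_mle <- local({
  cache <- new.env(parent = emptyenv())
  function(name, starts = 25) {
    if (is.null(cache[[name]])) {
      cache[[name]] <- gmoee_fit(gmoee_data(name), method = "mle",
                                 starts = starts, seed = 1)
    }
    cache[[name]]
  }
})

fixture_names <- c("aircon_boeing720", "nyc_ozone_1973", "wheaton_flood",
                   "covid_recovery_m60")
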