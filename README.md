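# gmoee

Tools for the **generalized Marshall–Olkin exponentiated exponential
(GMO-EE)** lifetime distribution: a four-parameter extension of the
exponential family for survival, reliability, hydrological and
epidemiological data whose hazard rate can be increasing, decreasing,
constant, bathtub, upside-down bathtub, or
increasing–decreasing–increasing. It is aimed at analysts who need a
flexible parametric lifetime model with closed-form quantiles, full moment
machinery, and several estimation routes that can be compared on the same
data.

## The model

The baseline is the exponentiated exponential EE(θ, β) with cdf
F(x) = (1 − e^(−θx))^β for x > 0, θ > 0 (rate), β > 0 (shape). The
generalized Marshall–Olkin transform adds a tilt parameter α ∈ (0, 1] and a
mixing parameter λ ∈ (0, 1]:

    G(x; α, λ, θ, β) = [λ F(x) + (1 − λ) F(x)²] / [α + (1 − α) F(x)]

with density

    g(x) = {(1 − α)(1 − λ)F² + 2α(1 − λ)F + αλ} / [α + (1 − α)F]² · f(x).

Setting λ = 1 recovers the classical Marshall–Olkin EE; α = λ = 1 gives
EE(θ, β); additionally β = 1 gives the exponential(θ). Solving G(x) = p is
a quadratic in F, so the quantile function is closed form and random
variates come from plain inverse-transform sampling.

The package provides:

* `dgmoee()`, `pgmoee()`, `qgmoee()`, `rgmoee()`, `sgmoee()`, `hgmoee()`
  (plus `dee()`/`pee()`/`qee()` for the baseline);
* moments: `gmoee_mean()`, `gmoee_variance()`, `gmoee_moment()`,
  `gmoee_mgf()`, `gmoee_incomplete_moment()`, `gmoee_lorenz()`,
  `gmoee_bonferroni()` — each with an adaptive-quadrature path (default)
  and a series-expansion path;
* five estimators behind one multistart harness — `gmoee_fit()` with
  `method = "mle"`, `"lse"`, `"wlse"`, `"ade"`, `"cvme"` — with broom-style
  `tidy()` / `glance()` and `autoplot()` methods;
* goodness-of-fit reporting (`gof_report()`, `gof_table()`) with
  −2 log L, AIC, Anderson–Darling, Cramér–von Mises and Kolmogorov–Smirnov
  statistics and approximate p-values, against EE, Weibull and exponential
  baselines;
* a Monte Carlo harness (`sim_design()`, `run_sim_study()`,
  `summarize_sim_study()`) for bias/MSE comparison of the estimators;
* four classical positive datasets (`gmoee_data()`): Boeing 720
  air-conditioning failure times, New York ozone levels, Wheaton River
  flood exceedances, and COVID-19 recovery times of males over 60;
* a command-line front end (`gmoee_cli()`, launcher in `inst/cli/gmoee`).

## Worked example

Fit the COVID-19 recovery times (50 males over 60, days from first
positive to first negative PCR test) and summarize the fitted model:

```r
library(gmoee)

fit <- gmoee_fit(gmoee_data("covid_recovery_m60"), method = "mle",
                 starts = 25, seed = 1)
fit
#> GMO-EE fit (MLE), n = 50
#>   alpha   0.0551 (0.0546)
#>   lambda  0.6797 (0.1964)
#>   theta   0.1079 (0.0280)
#>   beta    9.8301 (3.6863)
#>   logLik -173.3901  (-2log = 346.78)

e <- fit$estimate
gmoee_mean(e[["alpha"]], e[["lambda"]], e[["theta"]], e[["beta"]])
#> [1] 18.35088
100 * pgmoee(14, e[["alpha"]], e[["lambda"]], e[["theta"]], e[["beta"]])
#> [1] 44.62645
```

The fitted model says the mean recovery time is about **18.35 days** and
the probability of recovering within two weeks is about **44.6%**. The
model-comparison table shows the four-parameter model clearly dominating
the nested baselines on all three distance statistics:

```r
gof_table(gmoee_data("covid_recovery_m60"), starts = 25, seed = 1)
#>   model           k neg2loglik   aic    ad    cvm     ks    p_ad   p_cvm    p_ks
#> 1 GMO-EE          4       347.  355. 0.211 0.0276 0.0690 9.87e-1 9.83e-1 9.71e-1
#> 2 EE              2       352.  356. 0.689 0.112  0.115  5.68e-1 5.31e-1 5.18e-1
#> 3 Weibull         2       363.  367. 1.45  0.229  0.147  1.90e-1 2.18e-1 2.33e-1
#> 4 Exponential     1       391.  393. 6.31  1.21   0.347  6.94e-4 7.68e-4 1.17e-5
```

The same pipeline runs from a shell:

```sh
inst/cli/gmoee fit --fixture covid_recovery_m60 --method mle --seed 1
inst/cli/gmoee describe --eta 0.0551,0.6796,0.1079,9.8323
```

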