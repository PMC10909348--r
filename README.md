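# bsperc

Percentile inference for the two-parameter Birnbaum-Saunders
(fatigue-life) distribution.

## The problem

Positive, strongly right-skewed measurements — failure times under cyclic
stress, daily PM2.5 concentrations — are often better summarized by
percentiles than by a mean and variance: the median describes a typical
day, an upper percentile a bad one, and neither is dragged by the long
tail. The Birnbaum-Saunders distribution, with density

```
f(x; α, β) = 1/(2αβ√(2π)) · [(β/x)^(1/2) + (β/x)^(3/2)]
             · exp{ −(x/β + β/x − 2)/(2α²) },   x > 0,
```

fits such data well, and its percentile is available in closed form:

```
θ_p = (β/4) · (α z_p + √(α² z_p² + 4))²,   z_p = Φ⁻¹(p),
```

so θ_0.5 = β exactly. `bsperc` provides point estimation of (α, β) and
θ_p by maximum likelihood, and **four interval constructions** for θ_p:

| method | idea |
|---|---|
| `gci` | generalized confidence interval: empirical quantiles of simulated generalized pivotal quantities (a t(n−1) pivot for β via a quadratic in the √x-scale summaries, a χ²(n) pivot for α) |
| `bootstrap` | parametric bootstrap with twofold bias correction of the replicate MLEs, percentile interval of the corrected replicate θ's |
| `bayes` | equal-tailed credible interval from an exact generalized ratio-of-uniforms sampler for the marginal posterior of β (inverse-gamma priors on β and α²) plus the closed-form inverse-gamma conditional for α² |
| `hpd` | highest posterior density interval (shortest sorted window) on the same posterior draws |

A Monte Carlo engine (`bs_coverage_cell()`, `bs_coverage_grid()`)
measures coverage probability and average length of all four methods
under known parameters, and `bs_aic_table()` screens seven candidate
families by AIC. Two daily PM2.5 series from northern Thailand
(Mae Hong Son and Lampang provinces, 181 days each, January–June 2023)
ship as fixtures: `bs_dataset("maehongson")`, `bs_dataset("lampang")`.

## Worked example

```r
library(bsperc)
x <- bs_dataset("maehongson")     # 181 daily PM2.5 values, µg/m³

fit <- bs_fit(x, data = "maehongson")
fit
#> Birnbaum-Saunders maximum-likelihood fit
#>   data: maehongson (n = 181)
#>   alpha (shape) = 1.2484
#>   beta  (scale) = 32.6899
#>   log-likelihood = -903.4607   AIC = 1810.9213
```

The shape 1.25 indicates heavy right skew; the scale is the fitted
median: a typical day in this period saw about 33 µg/m³. Interval
estimates for the median by all four constructions:

```r
for (m in c("gci", "bootstrap", "bayes", "hpd"))
  print(bs_percentile_ci(x, p = 0.5, method = m, seed = 1))
#> 95% GCI interval for the 50-percentile
#>   [27.9424, 38.4062]   length 10.4639
#>   draws = 5000, seed = 1
#> 95% bootstrap interval for the 50-percentile
#>   [27.8213, 38.0270]   length 10.2057
#>   draws = 500, seed = 1
#> 95% Bayesian interval for the 50-percentile
#>   [28.1826, 37.9732]   length 9.7906
#>   draws = 5000, seed = 1
#> 95% HPD interval for the 50-percentile
#>   [27.9759, 37.7233]   length 9.7474
#>   draws = 5000, seed = 1
```

All four put the median PM2.5 between roughly 28 and 38 µg/m³. The HPD
interval is shortest — expected, since it is the shortest window by
construction — but the simulation engine shows the flip side: at small
n the bootstrap, Bayesian and HPD intervals buy their shorter length
with below-nominal coverage, while the GCI stays closest to 95%:

```r
bs_coverage_cell(n = 10, alpha = 0.5, reps = 500, seed = 1)
#>  n    p alpha beta level reps    method coverage avg_length
#> 10  0.5   0.5    1  0.95  500       gci    0.954     0.7054
#> 10  0.5   0.5    1  0.95  500 bootstrap    0.914     0.5632
#> 10  0.5   0.5    1  0.95  500     bayes    0.950     0.6557
#> 10  0.5   0.5    1  0.95  500       hpd    0.942     0.6385
```

Which family should model these data at all? AIC across seven
candidates:

```r
bs_aic_table(x)
#> AIC model comparison (lower is better; * marks the best family)
#>             family k     loglik      aic best
#>  birnbaum-saunders 2  -903.4607 1810.921    *
#>          lognormal 2  -907.0778 1818.156
#>        exponential 1  -916.4859 1834.972
#>            weibull 2  -916.2049 1836.410
#>              gamma 2  -916.4845 1836.969
#>             cauchy 2  -971.4702 1946.940
#>             normal 2 -1013.8996 2031.799
```

A command-line front end mirrors the API:

```sh
Rscript inst/cli/bsperc.R ci --method gci --p 0.5 --level 0.95 \
    --M 5000 --seed 1 --out ci.csv maehongson
Rscript inst/cli/bsperc.R aic-compare lampang
```

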