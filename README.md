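# siteuse

Bayesian site-use (occupancy) analysis of camera-trap surveys across
protection gradients, as one reusable R package: from raw time-stamped
photographs to model-averaged covariate effects with convergence and
spatial diagnostics — plus a synthetic-landscape generator with known truth
so every stage can be validated end to end.

The intended user is a quantitative ecologist analysing a single-season
camera-trap survey of an elusive species (the package defaults mirror a
127-station leopard survey spanning a national park, a wildlife management
area and village lands), or a methodologist who wants a fully testable
implementation of indicator-based Bayesian variable selection for occupancy
models.

## The model

For station *i* in sampling area *a(i)* and weekly occasion *j*:

    Z_i ~ Bernoulli(psi_i),      logit(psi_i) = alpha_{a(i)} + sum_c w_c alpha_c x_ic
    y_ij | Z_i ~ Bernoulli(Z_i p_ij),  logit(p_ij) = beta_0 + beta_k Trail_i

with area-level random intercepts `alpha_a ~ N(mu, tau^2)`, z-scored site
covariates `x_ic` (livestock presence, distance to river, distance to
household, prey CPUE), and Bernoulli(0.5) inclusion indicators `w_c`
(Kuo–Mallick construction) whose posterior means are the covariate
inclusion probabilities over the 2^C candidate models. Slopes and detection
coefficients carry Uniform(−10, 10) priors. The sampler is a compiled
Metropolis-within-Gibbs scheme (exact Gibbs for the latent `Z` and the
indicators), checked in the test suite against exhaustive likelihood
enumeration, a dense-grid posterior, and prior-recovery under an
uninformative survey. See `vignettes/site-use-methods.Rmd` for the full
account.

## Worked example

Simulate a survey at the default design scale (127 stations, 11 areas, 32
weekly occasions, ragged effort) and fit it:

```r
library(siteuse)

st  <- simulate_stations(seed = 1)
cv  <- simulate_covariates(st, seed = 2)
tr  <- synthetic_truth()      # mu -0.4, tau 1, slopes (-2, 0, +2, 0), beta0 -1.6
sim <- simulate_detection_data(st, cv, tr, seed = 3)

tabulate_by_zone(sim$history, sim$records, st)
#>            zone n_stations n_detected n_events effort_days
#> 1 national_park         76         42      248       12090
#> 2           wma         16          4       19        1243
#> 3  village_land         35          7       40        4127

fit <- fit_site_use(sim$history, sim$covariates,
                    area = st$area, trail = st$trail_type,
                    settings = mcmc_settings(3, 20000, 4000, 5, seed = 42))
summary(fit)
#>              parameter   mean    sd ci_low ci_high     w  rhat
#>       alpha[livestock] -2.230 1.543 -6.166  -0.224 0.531 1.000
#>      alpha[dist_river] -2.514 1.590 -5.981   0.157 0.398 1.003
#>  alpha[dist_household]  4.115 1.391  2.001   7.292 1.000 1.007
#>            alpha[cpue] -0.309 0.625 -1.904   0.652 0.065 1.000
#>  ...
#>                  beta0 -1.691 0.090 -1.873  -1.519    NA 1.001
#>               beta[NT]  0.013 0.220 -0.462   0.425 0.028 1.000
#>               beta[RD]  0.088 0.227 -0.337   0.513 0.031 1.000
#>           n_sites_used 60.753 2.641 56.000  66.000    NA 1.005
```

Reading the output: the selectable rows show the *conditional* posterior
(draws with the covariate included) next to its inclusion probability `w`.
The generating household effect (+2) is decisively included (`w = 1.00`)
and its interval excludes zero; the inert CPUE effect is switched off
(`w = 0.065`); detection sits at the generating `beta0 = -1.6` with inert
trail contrasts; and the estimated number of used sites (60.8 ± 2.6, 95% CI
56–66) brackets the 56 sites that truly drew `Z = 1` in this realization.
Every chain converges under the R-hat < 1.1 rule.

Prediction curves and residual correlograms:

```r
plot(predict_site_use_curve(fit, "dist_household"))

fit0 <- fit_site_use(sim$history, sim$covariates, area = NULL,
                     trail = st$trail_type,
                     config = site_use_config(random_intercept = FALSE),
                     settings = mcmc_settings(3, 20000, 4000, 5, seed = 42))
plot(distance_correlogram(site_residuals(fit0, st)))  # pooled model
plot(distance_correlogram(site_residuals(fit, st)))   # random intercept
```

The ingest side of the pipeline works from delimited text:
`read_records()` / `read_stations()`, `filter_independent()` (strict
5-minute chained burst filter), `compute_effort()` and
`build_detection_history()` for the weekly detection matrix, and
`compute_cpue()`, `compute_livestock_presence()`, `distance_raster()`,
`zscore_standardize()` and `collinearity_screen()` for the design matrix.

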