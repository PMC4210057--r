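# adstar

Structured additive regression (STAR) for daily district-level count data
with episodic environmental exposure — built for studies that ask whether
dust-storm (ADS) episodes raise clinic-visit counts after adjusting for the
weekly visit cycle, season, weather, ambient pollution and spatial
heterogeneity.

## Who this is for

Epidemiologists and biostatisticians with a district × day panel of visit
counts, a population denominator per district, a single-station daily
covariate series (CO, NOx, O3, PM10, SO2, temperature), a calendar of
declared storm events, and a district adjacency list. Because such claims
data are typically confidential, the package also ships a fully specified
synthetic-data generator with known truth, so the whole pipeline is
testable end to end.

## The model

Counts follow a Poisson structured additive model

```
Y_dt ~ Poisson(mu_dt)
log mu_dt = x_t' beta + z_t' gamma + f(t) + f(TP_t) + f_spat(d) + log POP_d
```

with

* `x_t` — intercept, six day-of-week dummies (Sunday reference), ADS-period
  and post-ADS-period indicators (events take precedence over the 7-day
  post window);
* `z_t` — selected pollutants, raw units; interquartile-range scaling only
  at reporting;
* `f(t)`, `f(TP)` — P-splines: B-spline bases with second-order
  random-walk (second-difference) penalties for calendar time and
  temperature;
* `f_spat(d)` — intrinsic CAR / Markov-random-field district effect
  (precision proportional to the graph Laplacian), sum-to-zero constrained;
* `log POP_d` — population offset.

Variances / smoothing parameters are estimated by REML (Fellner–Schall
updates, optional inverse-gamma damping); pollutant subsets are screened
for significantly positive coefficients and ranked by
`AIC = -2 loglik + 2 edf`. Effects are reported as percentage changes in
relative rate, `(exp(scale * coef) - 1) * 100`. See
`vignettes/star-methods.Rmd` for the full account.

## Worked example

```r
library(adstar)

sim <- generate_panel(sim_config(seed = 42, n_districts = 12,
                                 start = "2002-01-01", end = "2003-12-31"))
spec <- model_spec(pollutants = c("NOx", "O3"),
                   n_basis_time = 12, n_basis_temp = 10)
fit <- fit_star(build_design(sim$panel, sim$covariates, sim$calendar,
                             sim$graph, spec))
fit
#> Poisson STAR fit: 8760 observations, 42 coefficients
#>   log-likelihood -26023.78 | edf 34.75 | AIC 52117.06
#>   variances: f_time=0.005626, f_temp=0.003508, f_spat=0.3536
#>             estimate     se
#> (Intercept)  -6.8472 0.0090
#> I_MON         0.2393 0.0074
#> ...
#> I_ADS         0.0832 0.0096
#> I_POST_ADS    0.0253 0.0082

head(effect_report(fit), 10)
#>          term scale    pct      lo     hi
#> 1       I_MON   1.0  27.04  25.209  28.89
#> ...
#> 7       I_ADS   1.0   8.68   6.653  10.75
#> 8  I_POST_ADS   1.0   2.56   0.925   4.23
#> 9         NOx  26.2   4.20   3.650   4.74
#> 10         O3  11.7   6.61   6.024   7.21
```

Reading the output: the ADS-period estimate 0.0832 (log scale) means visit
rates were 8.68% higher (95% CI 6.65–10.75) on storm days than on ordinary
days — the generating truth here was `log(1.0948) = 0.0906`, comfortably
inside the interval. The `NOx` row says an interquartile-range (26.2 ppb)
increase in NOx is associated with a 4.20% higher visit rate. Spatial
effects come classified per district:

```r
table(spatial_effect_map(fit)$class)
#>       positive       negative nonsignificant
#>              6              6              0
```

and smoother curves with 80%/95% bands via
`smoother_curve(fit, "f_temp")`. The whole analysis — simulate, fit,
select pollutant subsets, report — also runs as one pipeline:

```r
run_pipeline(list(seed = 1), out_dir = "run1")   # writes CSV/JSON artifacts
```

or from the shell:

```sh
Rscript inst/cli/ads_star.R all --config cfg.json --out run1 --seed 1
```

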