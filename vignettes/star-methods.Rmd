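---
title: "Modelling dust-storm exposure and clinic-visit counts with structured additive regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dust-storm exposure and clinic-visit counts with structured additive regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adstar)
```

## The problem

Asian dust storms (ADS) episodically sweep high loads of particulate matter
and co-transported pollutants over Taiwan. Epidemiological interest centres
on whether daily counts of clinic visits — here, children's conjunctivitis
visits recorded per administrative district — rise during storm episodes
and in the week that follows, after adjusting for the strong weekly
clinic-visit cycle, seasonal trends, weather and ambient pollution. The
data layout this package targets is a district × day panel of counts with a
child-population denominator per district, a single-station daily covariate
series (CO, NOx, O3, PM10, SO2, mean temperature), a calendar of declared
dust-storm events, and a district adjacency structure.

## The model

Counts are modelled as Poisson with a structured additive predictor:

$$
Y_{dt} \sim \mathrm{Poisson}(\mu_{dt}), \qquad
\log \mu_{dt} = \mathbf{x}_{t}'\boldsymbol\beta + \mathbf{z}_{t}'\boldsymbol\gamma
 + f_T(t) + f_{TP}(TP_t) + f_{\mathrm{spat}}(d) + \log POP_d .
$$

* $\mathbf{x}_t$ holds the categorical fixed effects: six day-of-week
  dummies (Monday–Saturday, Sunday reference) and indicators for the ADS
  period (event days) and the post-ADS period (the 7 days after an event
  ends, with event days taking precedence when windows collide).
* $\mathbf{z}_t$ holds the selected pollutants in raw measurement units;
  interquartile-range scaling is applied only at reporting time so the
  coefficients stay unit-interpretable.
* $f_T$ and $f_{TP}$ are P-splines: cubic B-spline bases on equidistant
  knots with a quadratic penalty on second differences of the coefficients
  (the discrete analogue of a second-order random-walk prior). The penalty
  null space is {constant, linear}, so those shapes are never shrunk.
* $f_{\mathrm{spat}}$ carries an intrinsic conditional-autoregressive (CAR)
  prior: given all other districts, district $d$'s effect is Gaussian with
  mean the average of its $N_d$ neighbours and variance $\sigma^2/N_d$.
  Jointly this is an improper Gaussian whose precision is proportional to
  the graph Laplacian $K$ (diagonal $N_d$, $-1$ for neighbours); `fdᵀK f`
  equals the sum of squared neighbour differences.
* $\log POP_d$ is an offset with coefficient fixed at 1, converting counts
  to rates.

### Identifiability

Smooth terms and the spatial field are each confounded with the intercept
(and $f_T$, through its null space, with any linear drift). The package
keeps an explicit intercept and reparameterizes every penalized block with
a sum-to-zero constraint: the basis is rotated onto the null space of
$\mathbf{1}' B$, so any fitted smooth sums to zero over the observed
covariate values and the spatial field sums to zero over districts. One
consequence worth knowing: the constraint absorbs the *constant* member of
the RW2 null space, so a smooth whose truth is exactly linear collapses to
a block with effective degrees of freedom ≈ 1, not 2.

## Estimation

Fitting is empirical Bayes / REML, not MCMC:

1. **Inner loop** — for fixed variances $\tau^2_j$ (smoothing parameter
   $\lambda_j = 1/\tau^2_j$), penalized iteratively reweighted least
   squares maximizes the penalized Poisson log-likelihood, with
   step-halving whenever a step would increase the penalized deviance.
   Convergence: relative change in penalized deviance `< 1e-8`
   (max 100 iterations).
2. **Outer loop** — each block's variance is updated by the Fellner–Schall
   REML step
   $\tau^2_j \leftarrow \dfrac{\hat\beta_j' K_j \hat\beta_j}
   {\mathrm{rank}(K_j) - \lambda_j\,\mathrm{tr}(H^{-1} K_j)}$,
   where $H$ is the penalized information; its fixed point is the
   stationary point of the Laplace-approximate restricted likelihood.
   Convergence: relative change in all $\tau^2_j$ `< 1e-6`
   (max 200 outer iterations, exceeded → error).
3. **Inverse-gamma damping** — the variances may optionally (and by
   default) be damped by an IG(0.001, 0.001) prior, adding $2b$ to the
   numerator and $2a$ to the denominator of the update. This honours the
   hyperprior the estimation literature pairs with this model class and
   stabilizes blocks whose coefficients are near zero; it also keeps
   variances strictly positive, which is why the "linear truth ⇒ edf → 1"
   limit is only exact with damping off (`control = list(use_ig = FALSE)`).

The posterior covariance is the inverse penalized information at
convergence (the usual empirical-Bayes Gaussian approximation); standard
errors, credible bands for smoothers, and the spatial classification all
derive from it. Effective degrees of freedom per block are traces of the
corresponding hat-operator blocks, and
$\mathrm{AIC} = -2\hat\ell + 2\,\mathrm{edf}_{\mathrm{total}}$. In the
unpenalized special case the whole machinery reduces exactly to a Poisson
GLM, which the test suite verifies against `stats::glm` at `1e-6`.

## Pollutant-subset selection

All $2^5 - 1 = 31$ non-empty subsets of {CO, NOx, O3, PM10, SO2} are
fitted (`strategy = "all_subsets"`; a staged variant reproducing the
narrated single-pollutant-then-combinations procedure is also available).
A candidate survives screening only if *every* pollutant coefficient is
significantly positive (95% Gaussian interval above zero — the
significance criterion is a package choice, the source analysis does not
state one); survivors are ranked by AIC, ties broken toward smaller
subsets. Non-converged fits are excluded with their error message
recorded, and an empty eligible set is a reported outcome, not an error.

## Reporting scales

* Fixed effects: percentage change in relative rate,
  $(\exp(\hat\beta) - 1)\times 100$, CI endpoints transformed
  monotonically.
* Pollutants: the same transform at the interquartile-range scale,
  $(\exp(\mathrm{IQR}\cdot\hat\gamma) - 1)\times 100$. The IQR uses
  linear-interpolation quantiles (R type 7), computed over all study days
  by default (whether the original station summaries excluded missing days
  is unknowable from the publication; both options are supported).
* Spatial effects: $RR_d = \exp(\hat f_{\mathrm{spat}}(d))$ with a 3-way
  classification — positive / negative / non-significant according to
  whether the 95% posterior interval lies above 1, below 1, or contains 1.
  Classification happens on the log scale and is exponentiated afterwards
  (equivalent, avoids overflow).
* Smoothers: $\exp(\hat f)$ on a grid with pointwise 80% and 95% bands.

## The synthetic world

The generator exists so that every stage is testable without the
confidential claims data. Its defaults state one fixed world:

* 41 districts on a rook-adjacency lattice (6×7 grid minus one cell) — a
  documented synthetic stand-in for the unpublished study-area adjacency,
  also shipped as `extdata/taipei41_synthetic_adjacency.txt`;
* the 2002–2007 calendar (2191 days) with the packaged 30-event storm
  fixture;
* district child populations log-uniform on 2,000–50,000, spanning the
  spread implied by the published crude-rate range;
* baseline visit rate $10^{-3}$ per child-day (100 per 100,000, mid-range
  of the published crude rates);
* day-of-week multipliers, ADS (+9.48%) and post-ADS (+2.32%) effects, and
  NOx/O3 coefficients back-transformed from the published schoolchildren
  estimates;
* pollutants drawn per day from the period-specific published means/SDs,
  truncated at zero with the latent location shifted so the truncated mean
  equals the configured mean (plain truncation would bias SO2's
  "other"-period mean by ≈2 standard errors — the generator must reproduce
  its own regime);
* temperature as a seasonal sinusoid (mean 23 °C, amplitude 7 °C, peak
  mid-July, noise SD 1.5 °C) matching the published temperature range;
* a temperature effect bump peaking near 28 °C with maximum log-RR 0.15
  and a slow sinusoidal calendar-time trend of amplitude 0.15 — shapes
  chosen qualitatively (warm-season excess), with no numeric values read
  off published figures;
* a CAR spatial field with $\sigma^2 = 0.25$, a moderate field.

What the generator deliberately does **not** emulate: day-to-day pollutant
autocorrelation (an AR(1) option exists but defaults off), within-week
count autocorrelation beyond the day-of-week dummies, overdispersion, and
any attempt to match the real claims series beyond the printed summary
statistics. A green simulation test therefore establishes that the
estimation machinery recovers the stated world — not that the original
epidemiological estimates are reproduced, which is impossible without the
confidential data.

For the selection-consistency experiment, "strong effects" are defined
once as three times the back-transformed published NOx/O3 coefficients on
an 8-district × 365-day panel; at published strength on a desk-scale panel
the signal is genuinely too weak for consistent subset recovery, which is
a property of the design, not of the implementation.

## Numerical choices and degenerate inputs

* Equidistant knots with `degree`-fold exterior extension; boundary knots
  pinned exactly to the data range so boundary evaluation is admissible;
  out-of-domain evaluation errors unless `clamp = TRUE`.
* IRLS weights floored at `1e-10`; Cholesky solves with a tiny ridge
  retry; linear predictors capped at 700 before exponentiation inside
  step-halving.
* Variances floored at `1e-10` (clamped with a warning — this is the
  "smooth wants to vanish" limit) and capped at `1e8`.
* Isolated districts are a hard error for the CAR structure by default
  (the intended study areas are contiguous); `allow_isolated = TRUE`
  keeps them with a zero Laplacian row, but conditional moments remain
  undefined there.
* Duplicate/reversed adjacency edges collapse; self-loops error.
* Ties in AIC ranking break toward the smaller subset, then
  lexicographically, so selection is deterministic.
* Same-day pollutant exposure is the default; a `pollutant_lag` option
  exists but no lag value is taken from the source analysis.

## Limitations

* Empirical-Bayes intervals ignore smoothing-parameter uncertainty; for
  smooths estimated near their null space the bands can undercover.
* AIC uses effective degrees of freedom; a software stack that counted raw
  parameters would rank models slightly differently.
* The CAR field and the calendar-time smooth compete for slow spatial-mean
  drift; the sum-to-zero constraints resolve the aliasing but joint
  confounding with unmeasured slow covariates is, as always, untestable.
* No overdispersion handling: a quasi-Poisson or negative-binomial variant
  would be the first extension for real claims data.
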