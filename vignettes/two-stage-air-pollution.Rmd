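---
title: "Two-stage Bayesian exposure and quasi-Poisson health-effect models"
author: "airhealth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Bayesian exposure and quasi-Poisson health-effect models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Time-series studies of air pollution and hospital admissions need a single
daily exposure value per city, but what is actually measured is a network of
9–15 monitors reporting noisy, spatially heterogeneous, sometimes missing
concentrations. Averaging the monitors ignores both measurement error and
the spatial structure of the pollution field, and the resulting
errors-in-exposure can bias the estimated health effects. `airhealth`
implements a two-stage design around this problem:

1. **Stage 1** — a hierarchical Bayesian spatio-temporal model estimates the
   latent daily pollution level from the monitor panel by MCMC.
2. **Stage 2** — quasi-Poisson time-series regressions relate daily
   admission counts to the (lagged) estimated exposure, adjusting for
   calendar time, meteorology and day of week, and report the percent
   change in relative risk per 10 μg/m³.

The two stages are deliberately decoupled: the expensive exposure model is
fitted once per pollutant and city, and any number of health models (lags,
strata, pollutant combinations) are then fitted against its output.

## Stage 1: the exposure model

Let \(W_{st}\) be the observed concentration at site \(s\) on day \(t\).
Concentrations are positive and right-skewed, so the model works on
\(Y_{st} = \ln W_{st}\):

\[
Y_{st} \sim N(Z_t + m_s,\ \sigma^2_\varepsilon),
\qquad
Z_t \sim N(\mu + \rho (Z_{t-1} - \mu),\ \sigma^2_z),
\qquad
m \sim \mathrm{MVN}(0,\ \sigma^2_m \Sigma(\phi)),
\]

with \(\Sigma(\phi)_{ss'} = \exp(-\|s - s'\|/\phi)\) — the Matérn kernel
with smoothness fixed at 0.5, i.e. the exponential kernel on Euclidean
distance in km. Priors are \(\mathrm{IG}(0.01, 0.01)\) on the three
variances and a discrete uniform prior on \(\phi\) over a grid spanning the
minimum to the maximum pairwise monitor distance. The reference protocol
runs 40,000 iterations and discards 10,000 as burn-in; these are the
defaults of `mcmc_config()`.

### Sampler design

* The whole latent path \(Z_{1:T}\) is updated **jointly** by
  forward-filter backward-sampling (FFBS) rather than one day at a time:
  with \(T \approx 1100\) daily states, single-site updates mix far too
  slowly. \(Z_1\) takes the stationary prior
  \(N(\mu, \sigma^2_z/(1-\rho^2))\), which makes the AR(1) likelihood
  proper. The recursion is implemented in C++ and uses R's RNG, so runs are
  bit-reproducible under a seed.
* Site effects are drawn jointly from their multivariate-normal full
  conditional. Because the likelihood only identifies \(Z_t + m_s\) up to a
  constant exchanged between the two, the sampler by default recentres
  \(m\) to sum to zero each sweep and transfers the removed mean into
  \(Z\). This leaves the likelihood untouched and removes the additive
  confounding between the level \(\mu\) and the site effects. A
  consequence worth knowing when validating against simulations: for a
  given dataset the identified level is the realized grand level
  \(\mu + \bar m\), and that is the quantity the \(\mu\)-interval should be
  compared against (our coverage tests do exactly this).
* \(\mu\) is given a diffuse conjugate \(N(0, 10^4)\) prior and
  \(\rho\) a flat prior on \((-1, 1)\); neither is dictated by the model
  protocol, and these choices preserve full conjugacy. The \(\rho\) update
  uses the conditional linear-regression form on the centred path (terms
  \(t \ge 2\), truncated to \(\pm 0.999\)). Dropping the stationary
  first-day factor keeps the update conjugate; with daily series hundreds
  to thousands of days long the effect of that single term is negligible.
  Our sampler-validation (Geweke-style) experiment therefore holds
  \(\rho\) fixed and validates the \(\rho\) update separately against its
  closed-form target.
* \(\phi\) is updated by griddy Gibbs: the discrete conditional is
  evaluated at every grid value, normalised by max-subtraction and sampled
  categorically. All \(\Sigma(\phi_k)\) Cholesky factorisations, log
  determinants and inverses are cached once per run, since the grid is
  fixed by the network. The grid resolution is not part of the protocol;
  the default is 50 points, configurable via `phi_grid_size`.
* Missing observations are **marginalized**, not imputed: a missing cell
  simply contributes no likelihood term. Whole missing days are handled by
  the filter's predictive step, and late-start stations (block
  missingness) by per-site observation counts.
* Numerical safeguards: correlation matrices get an escalating diagonal
  jitter (1e-10 up to 1e-6) before factorisation; initialization uses
  moment estimates with variances floored at 1e-4 and \(\rho\) clipped to
  \((-0.99, 0.99)\); days with no observations are bridged by linear
  interpolation at initialization only.

### Back-transformation

The stage-1 → stage-2 handoff is a daily concentration-scale series.
`summarize_exposure()` defaults to the posterior mean of \(\exp(Z_t)\)
("mean-of-exp"), the consistent estimator of the concentration-scale
level; `exp-of-mean` (the exponential of the posterior mean of \(Z_t\)) is
provided for sensitivity analyses. Spread and interval columns always come
from the exponentiated draws.

## Stage 2: the health model

Daily admission counts \(y_t\) are modelled as quasi-Poisson with log link:

\[
\log E[y_t] = \alpha + \beta\, x_{t-\ell} + s(t; 7\,\mathrm{df/yr}) +
s(\mathrm{temp}; 4) + s(\mathrm{RH}; 4) + s(\mathrm{wind}; 3) +
s(\mathrm{pressure}; 5) + \mathrm{DOW}_t,
\]

where \(x\) is the exposure in μg/m³ at lag \(\ell \in \{0,\dots,6\}\) and
the \(s(\cdot)\) are natural cubic splines with fixed degrees of freedom
(calendar time gets `round(7 × years)` df, with years counted as
days/365.25). Day-of-week enters as six dummies with Monday as reference;
holidays are not modelled. There is no population offset — the intercept
absorbs the baseline. The fit is unpenalized maximum likelihood via IRLS
(identical point estimates to a plain Poisson fit); overdispersion enters
only through the Pearson-based dispersion factor scaling the covariance.
Effects are reported as \(100(\exp(10\beta) - 1)\) percent per 10 μg/m³
with Wald 95% intervals transformed from the log-RR scale — hence
reported intervals are always symmetric on that scale, which is also how a
published interval's upper bound can be reconstructed from its estimate
and lower bound.

Knot placement for the splines is not part of the protocol; we use the
dominant convention in time-series epidemiology (boundary knots at the
data range, interior knots at equally spaced quantiles). The protocol
lists fixed df; an optional `qaic_scan()` (QAIC = deviance/dispersion +
2p, dispersion taken from the largest candidate) is provided for
sensitivity, without any claim that it reproduces the original df
selection. Multipollutant fits enter 2–4 exposures jointly at the same
lag and refuse near-collinear pairs (|r| > 0.999). All seven lags are
always reported; no automatic lag selection is performed beyond flagging
the minimum-p lag in metadata. p-values are two-sided Wald and no
multiplicity adjustment is applied (results carry unadjusted 95% CIs).

## Monitor geometry

The exponential kernel is defined on planar Euclidean distance, so
geographic coordinates are projected to local km. We use an
azimuthal-equidistant projection about the coordinate centroid rather than
the simpler equirectangular form: at mid-latitudes (~36°N) the
equirectangular projection distorts east–west distances on a one-degree
box by up to ~0.6%, while the azimuthal-equidistant error at sub-100 km
study extents is orders of magnitude below the 0.5% accuracy we require of
the geometry layer at any latitude.

## The synthetic test bed

No admission or monitor data are distributed, so the package ships a
generator with known ground truth that emulates the study conditions:

* **Networks**: uniformly scattered sites, rescaled so the maximum
  pairwise distance matches the study geometries (15 sites / 74.64 km
  inland; 9 sites / 87.64 km coastal).
* **Exposure field**: the generative direction of the stage-1 model. The
  coastal-like truth is \(\mu = \ln 30\), \(\rho = 0.6\),
  \(\sigma^2_\varepsilon = 0.05\), \(\sigma^2_z = 0.12\),
  \(\sigma^2_m = 0.04\), \(\phi = 25\) km — synthetic values chosen to give
  realistic day-to-day and site-to-site spreads, not estimates from any
  dataset. The inland-like truth shifts the level to \(\mu = \ln 44\),
  matching the reported median NO₂ concentration there, and keeps the same
  dynamics.
* **Meteorology**: annual sinusoids plus AR(1) noise with plausible
  mid-latitude constants (temperature peak mid-July, pressure peak winter,
  RH clipped to [5, 100]).
* **Admissions**: negative-binomial counts (quasi-Poisson is not
  generative) around baselines matching the reported daily medians (291
  inland, 80 coastal), NB size 150 and 80 respectively — mild-to-moderate
  overdispersion so that fitted stage-2 dispersions exceed 1. The log
  intensity adds the true exposure effect
  \(\beta = \ln(1 + \mathrm{pct}/100)/10\) (presets default to printed
  effect sizes), a winter-peaking seasonal cycle, day-of-week effects, and
  mild centred-quadratic meteorology effects — strong enough to exercise
  the confounder adjustment without dominating the exposure signal. Every
  non-baseline term is centred so the baseline is the marginal scale. Sex
  (0.55/0.45) and age (0.53/0.47) strata are binomial splits that re-sum
  exactly to the total; the proportions are synthetic conveniences of the
  right order of magnitude.

What the generator deliberately does **not** emulate: pollution chemistry
and co-emission correlation between pollutants, seasonality of the
exposure itself (the latent field is a stationary AR(1)), city topography,
holidays, reporting artefacts or policy shocks. Passing recovery tests
therefore demonstrate that the estimators are calibrated under the model's
own assumptions plus realistic noise scales — not that the original
epidemiological estimates are reproduced, which would require the
confidential data.

## Experiment sizes and calibration results

The packaged experiments use reduced-but-faithful problem sizes chosen so
the whole suite runs comfortably on a single CPU: stage-2 recovery uses
the full 1096-day, 291-counts/day inland scale over 50 replicates;
two-stage recovery uses 9 sites × 730 days with 4,000-iteration /
1,000-burn-in chains over 20 replicates; credible-interval coverage uses
the same reduced chains over 20 replicates; the null-calibration suite
uses 200 one-year replicates. The corresponding checks — recovery of
2.647%, 6.568% and 0.316% generative effects within Monte-Carlo error,
≥16/20 coverage for \((\mu, \rho, \sigma^2_\varepsilon, \sigma^2_z)\),
type-I error inside (0.02, 0.10) — are exactly what
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` compute;
this vignette reports no numbers beyond what those runs produce.

## Known limitations

* One latent field per pollutant per city: no multi-pollutant joint field,
  no spatio-temporal interaction, no prediction at unmonitored locations,
  no kriging and no anisotropy.
* The \(\rho\) update's conditional form drops the stationary first-day
  term (see above); exact for practical purposes at daily-series lengths,
  but not literally the joint-model conditional.
* Stage 2 propagates only the posterior *mean* exposure series, in line
  with the two-stage protocol; exposure uncertainty is not propagated into
  the health-model intervals, and a small attenuation of health effects
  from residual exposure smoothing is expected and observed to be well
  within Monte-Carlo error at the packaged scales.
* Distributed-lag nonlinear models, case-crossover designs and
  meta-analysis across cities are out of scope.
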