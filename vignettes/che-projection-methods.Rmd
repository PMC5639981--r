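---
title: "Methods: projecting catastrophic health expenditure incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting catastrophic health expenditure incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Catastrophic health expenditure (CHE) — out-of-pocket medical spending that
exceeds roughly 40% of a household's capacity to pay — is the standard
indicator of weak financial risk protection. Its country-level incidence is
driven by a small number of macro-financial quantities: the out-of-pocket
share of total health expenditure (`OOP_EXP`), the health expenditure share
of GDP (`HEX_GDP`), and GDP per capita (`GDP_C`). `cheproj` provides the
machinery to (i) estimate that relationship on a country-year panel,
(ii) project CHE incidence forward to a horizon year (by default 2040)
given external covariate forecasts, (iii) quantify uncertainty around the
projections by Monte Carlo simulation, and (iv) evaluate how likely each
World Bank income group (LIC, LMIC, UMIC, HIC) is to attain candidate
financial-risk-protection targets, with and without policy counterfactuals.

## The model

The core regression is a linear mixed model on the logit scale:

$$\operatorname{logit}(\mathrm{CHE}_{it}) = \beta_0
 + \beta_1\,\operatorname{logit}(\mathrm{OOP\_EXP}_{it})
 + \beta_2\,\operatorname{logit}(\mathrm{HEX\_GDP}_{it})
 + \beta_3\,\ln(\mathrm{GDP\_C}_{it}) + b_i + \varepsilon_{it},$$

with $b_i \sim N(0, \tau^2)$ a country random intercept absorbing
between-country heterogeneity and $\varepsilon_{it} \sim N(0, \sigma^2)$ a
residual. All shares enter as proportions strictly inside (0, 1); a
configurable clipping bound (default $10^{-6}$) handles boundary values
where the logit is undefined. Because both outcome and the two share
covariates are on the logit scale, slopes have a direct odds
interpretation: a relative change $c$ in the odds of a predictor changes
the outcome odds by $(1+c)^{\beta}-1$ (`odds_effect()`). This is an
odds-ratio statement, not a risk-ratio approximation — with a rare outcome
the two nearly coincide, but the implementation and documentation are
deliberate that the odds scale is the one modelled.

Estimation uses `lme4::lmer`. REML is the default (standard for variance
components); ML is available for likelihood comparisons. Coefficient
p-values use the two-sided normal approximation on estimate/SE; no
degrees-of-freedom correction is attempted since downstream use of the fit
is simulation, not hypothesis testing. A near-zero random-effect variance
(singular fit) is reported with a warning and the model degrades gracefully
to a fixed-effects fit. The goodness-of-fit statistic is a
variance-decomposition R²: the marginal version (default) is
$\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \hat\tau^2 +
\hat\sigma^2)$; the conditional version credits $\hat\tau^2$ to the
numerator and is never smaller.

## Deterministic projection

The point projection proceeds in three steps:

1. **Growth annualisation.** Each country's multi-year GDP-per-capita run
   (e.g. IMF projections over 2015–2021) is reduced to a constant annual
   rate. The default is the endpoint geometric rate
   $(v_\mathrm{last}/v_\mathrm{first})^{1/\Delta t}-1$; a log-linear OLS
   alternative over all years is switchable (`annualization: ols_log`).
   Rates are then summarised per income group by mean and sample SD
   (n−1 denominator).
2. **Covariate projection.** Horizon-year GDP per capita is the base-year
   value compounded at the *group* mean rate — deliberately per group, not
   per country, so all members of a group share one growth assumption.
   `OOP_EXP` and `HEX_GDP` come from external forecasts as mean plus 95%
   interval. The base year defaults to the last panel year (2013) with a
   27-year horizon to 2040; both are configurable.
3. **Prediction and aggregation.** Each country's horizon CHE is the
   inverse-logit of the fitted linear predictor at its forecast
   covariates; the group value is the *unweighted arithmetic mean* of its
   member countries (countries, not populations, are the units — this is
   asserted exactly in the tests, not approximately). Country random
   intercepts default to zero in projections (population-level
   prediction); a `use_blup` switch carries each country's estimated
   intercept forward instead.

Annualised decline rates between the base-year level $s$ and horizon level
$e$ use $r = 1-(e/s)^{1/n}$, and the cumulative relative reduction over
$n$ years is $1-(1-r)^n$; the two are exact inverses. Because it is
unstated whether published group-level reductions were derived from group
levels or from rounded annual rates, both paths are exposed
(`compute_decline()` on levels, `cumulative_decline()` on a rate). The
base-year group level itself can be computed two ways — the mean of
*observed* base-year CHE, or the mean of model-*fitted* values with BLUPs
— and `baseline_group_che()` labels which one it returns, since the data
average and the model-implied level answer slightly different questions.

## Monte Carlo uncertainty propagation

The probabilistic sensitivity analysis samples, per trial:

* one coefficient vector from $N(\hat\beta, \widehat{\mathrm{cov}}(\hat\beta))$
  (estimation uncertainty). The matrix square root is a symmetric eigen
  decomposition; eigenvalues in $[-10^{-10}, 0)$ are treated as rounding
  and clipped to zero, anything more negative is an error;
* per country, one `OOP_EXP` and one `HEX_GDP` value from beta
  distributions fitted to the forecast mean and 95% interval;
* per income group, one GDP growth rate from a gamma distribution
  moment-matched to the group's mean and SD of annualised growth
  (shape $=(\mu/\sigma)^2$, scale $=\sigma^2/\mu$). One draw is shared by
  all group members within a trial, mirroring the per-group fitting of the
  growth distribution; a per-country-draw variant is switchable.

Covariate draws are independent across countries and between the two
shares within a country — no correlation structure is claimed. The
residual $\varepsilon$ and fresh random-intercept draws are *excluded* by
default: the propagated uncertainty is input-parameter plus coefficient
uncertainty about the expected incidence, not observation noise. An
`include_residual` flag adds the residual for sensitivity analysis.

Group trial values are the unweighted row-means of member-country trials
(the aggregation is conserved bit-exactly, and tested as an identity).
95% uncertainty intervals are the 2.5th and 97.5th percentiles with linear
interpolation between closest ranks (R quantile type 7) — fixed so outputs
are stable across runs and platforms. Target attainment probabilities are
the fraction of trials with group CHE *strictly* below each threshold
(defaults 0.5%, 1%, 1.5%, 2%), matching the strict inequality with which
such targets are stated; gap-closing probabilities compare decline rates
pairwise within trials (strict `>`, ties count as failures), preserving
the coefficient-draw correlation between groups. Per-trial decline rates
re-predict the base-year group CHE inside each trial from the same
coefficient draw (`decline.baseline: per_trial`, the default), so baseline
and endpoint are coherently correlated; a fixed-baseline variant divides
by a constant instead.

### Beta fitting from a mean and interval

A beta distribution is pinned down by the stated mean exactly — the
parameterisation is $\alpha = m\kappa$, $\beta = (1-m)\kappa$ — and the
concentration $\kappa$ is found by 1-D least squares on the 2.5th/97.5th
quantiles, initialised from the moment estimate with
$\mathrm{sd}_0 = (\mathrm{hi}-\mathrm{lo})/3.92$. The criterion is this
package's choice; with one free parameter an asymmetric interval cannot be
matched exactly, so residuals are always reported and a fit far from the
stated bounds errors unless explicitly relaxed. Zero-width intervals
become flagged point masses whose "samples" are the mean. Intervals that
have been clipped at a policy cap are top-censored (no beta matches them);
these use the relaxed fit and their draws are clipped at the cap, which
realises the censored distribution directly.

## Policy scenarios

The one modelled lever is a cap on the horizon-year out-of-pocket share.
`apply_oop_cap()` clips the forecast mean and both interval bounds at the
cap for targeted income groups, records the cap so the Monte Carlo engine
can clip sampled values at it as well (a capped covariate can never be
sampled above the cap), and never mutates its input. With a positive
out-of-pocket slope, tighter caps can only lower projected group CHE and
raise attainment probabilities — both monotonicities are tested.

## The synthetic-data generator

No country-level input data ship with the package, so the generator
produces the three input tables — panel, horizon forecasts, GDP runs —
from a known ground truth, and is itself first-class, tested code. It
simulates the exact forward model above: one random intercept per country,
covariates drawn per group (beta for the two shares, log-normal for GDP
per capita), and the logit-linear outcome with residual noise, then
removes a configured fraction of CHE observations.

Defaults are fixed once and documented rather than tuned: 32/45/51/51
countries in LIC/LMIC/UMIC/HIC, years 1995–2013, slopes
$(\beta_1,\beta_2,\beta_3) = (0.67,\,0.67,\,-0.38)$, random-intercept
variance 0.29, and per-group annual GDP growth means (SDs) of 4.5% (2.9),
4.5% (2.7), 4.1% (2.4) and 3.4% (2.0). The intercept $\beta_0 = 0$ is
chosen so that typical low-income covariates (out-of-pocket share ≈ 0.45,
health share ≈ 0.055, GDP per capita ≈ 800) imply a CHE incidence near 1%,
a realistic order of magnitude. The residual SD of 0.5 on the logit scale
is "moderate noise": combined with the covariate spreads it yields
marginal R² values around 0.6–0.7 on generated panels. Per-group covariate
distributions encode the qualitative gradient that poorer groups carry
higher out-of-pocket shares and lower GDP; they are documented constants,
not estimates of any real dataset. CHE missingness defaults to 0.3,
reflecting that such panels observe the outcome far less often than the
covariates.

Covariates are drawn independently across years within a country, as the
model treats them as exogenous regressors; an AR(1) hook (`ar1_rho`, via a
latent Gaussian copula so the marginal distribution is preserved) exists
for robustness studies. Growth draws are truncated above −100% so GDP
stays positive. Forecast means are the true horizon covariates perturbed
on the logit scale by $N(0, 0.15^2)$, with intervals symmetric on the
logit scale of half-width $1.96 \times 0.15 \times$ `ui_width_factor` — at
the default factor of 1 the intervals are calibrated to the injected
noise, which is what makes the interval-coverage property testable.

What passing tests on this generator do and do not show: they demonstrate
that the estimation, projection and uncertainty machinery is correct
*under the assumed model* — unbiased coefficient recovery, calibrated Wald
intervals, conserved aggregation, stable Monte Carlo percentiles. They do
not validate the model against real data, where covariates trend over
time, CHE measurement error is not log-normal, income-group membership
changes, and forecast intervals are not calibrated by construction.

## Numerical choices and problem sizes

* Proportions live in (0, 1) internally; percent-scale files are converted
  only under an explicit `percent_input` flag, never by magnitude
  guessing.
* The Monte Carlo default is 100,000 trials. Validation simulations are
  sized to what the properties need: 5,000 trials for degeneracy checks,
  100,000 for seed-stability (binomial MC error ≈ 0.002), 200 replicates
  for coefficient-recovery coverage — at a true 2-SE coverage near 95% a
  small replicate set has binomial noise of several percentage points, so
  coverage is estimated at n = 200 where its standard error is ≈ 1.5%.
* All randomness flows through explicit integer seeds; generation,
  forecasting and projection derive distinct sub-seeds so stages can be
  re-run independently. Draw order within the Monte Carlo engine
  (coefficients, then group growth, then per-country covariates in sorted
  country order) is fixed and documented, making runs bit-reproducible.
* The run log records package and R versions, seeds and row counts.

## Known limitations

* The intercept and residual variance of the published model are not
  recoverable from printed tables, so projections of the published
  2040 levels cannot be reproduced without the original country inputs;
  the package validates against in-print worked examples and synthetic
  ground truth instead.
* Group aggregation is country-weighted only; population weighting is out
  of scope.
* The beta interval fit has one free parameter after the mean constraint;
  strongly asymmetric intervals are matched in least squares, not exactly.
* No year-by-year interpolation between base and horizon years — the
  method reports endpoints and annualised summaries only.
* Policy caps are static horizon-year caps; dynamic phase-in paths are not
  modelled.
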