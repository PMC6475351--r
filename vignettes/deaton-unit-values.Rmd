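---
title: "Estimating price elasticities from unit values: methods and design"
author: "deatonuv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating price elasticities from unit values: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Household expenditure surveys in low- and middle-income countries rarely
record the prices households face, but they do record how much was spent on a
good and how much was bought. The ratio of the two — the *unit value*
$v_{ic} = \mathrm{expenditure}_{ic} / \mathrm{quantity}_{ic}$ for household
$i$ in cluster $c$ — is a price proxy. It is a contaminated one: richer
households buy dearer varieties (*quality shading*), so unit values rise with
income even at fixed prices, and recall errors in either the numerator or the
denominator show up directly in the ratio. Deaton's method turns unit values
into usable price variation by exploiting the survey's cluster design:
within a village prices are essentially constant, while transport costs make
them differ *between* villages. Price elasticities are then identified from
between-cluster comovement of demand and unit values, after quality and
measurement-error corrections. `deatonuv` implements that pipeline for a
single good (cigarettes, in the motivating Uganda application), together
with a synthetic-survey generator with known ground truth so every stage can
be tested without restricted microdata.

## The model

The within-cluster stage fits the two-equation linear-approximate AIDS
structure

$$\ln v_{ic} = \lambda + \beta \ln x_{ic} + \gamma' Z_{ic} + \psi \ln \pi_c + e_{ic},$$
$$w_{ic} = \alpha + \varepsilon \ln x_{ic} + \delta' Z_{ic} + \theta \ln \pi_c + (FE_c + u_{ic}),$$

where $x_{ic}$ is total weekly household expenditure, $w_{ic}$ the cigarette
budget share, $Z_{ic}$ household covariates, $\ln \pi_c$ the unobserved
cluster log price and $FE_c$ a cluster taste effect. Both equations are
estimated by within-cluster demeaning, which sweeps out everything constant
within a cluster — the unobserved prices and the taste effects — exactly.
$\beta$, the slope of the log unit value in log expenditure, is the
expenditure elasticity of *quality*: a positive estimate is direct evidence
of quality shading.

The between-cluster stage strips the estimated household-level effects and
averages by cluster,

$$\hat y^1_c = \tfrac{1}{n_c}\sum_i (\ln v_{ic} - \hat\beta \ln x_{ic} - \hat\gamma' Z_{ic}), \qquad
  \hat y^2_c = \tfrac{1}{n_c}\sum_i (w_{ic} - \hat\varepsilon \ln x_{ic} - \hat\delta' Z_{ic}),$$

and estimates the slope of demand on the price proxy with an
errors-in-variables correction:

$$\hat\phi = \frac{\mathrm{Cov}(\hat y^2, \hat y^1) - \hat\sigma_{12}\,\overline{1/n_c}}
                  {\mathrm{Var}(\hat y^1) - \hat\sigma_{11}\,\overline{1/n^+_c}}.$$

Cluster averages of $\ln v$ carry averaged household-level noise whose
variance is $\sigma_{11}/n_c$; left uncorrected it attenuates the ratio.
$\hat\sigma_{11}$ and $\hat\sigma_{12}$ are the residual variance of the
unit-value equation and the residual covariance of the two equations, with
degrees of freedom $n - k - C$ (slopes plus absorbed fixed effects). With
unbalanced clusters the correction uses the mean of the reciprocal counts,
the standard treatment for this estimator.

Finally the quality-correction formulas recover the structural price slopes
and the elasticities:

$$\hat\zeta = \frac{\hat\beta}{\hat\varepsilon + \bar w (1 - \hat\beta)}, \qquad
  \hat\theta = \frac{\hat\phi}{1 + (\bar w - \hat\phi)\hat\zeta}, \qquad
  \hat\psi = 1 - \frac{\hat\beta(\bar w - \hat\theta)}{\hat\varepsilon + \bar w},$$

$$\hat\varepsilon_P = \frac{\hat\theta}{\bar w} - \hat\psi, \qquad
  \hat\varepsilon_I = 1 + \frac{\hat\varepsilon}{\bar w} - \hat\beta,$$

with $\bar w$ the unweighted sample mean budget share. The flattened
typography in which these formulas usually circulate admits several
groupings; the forms above are the canonical ones and are internally
consistent: the chain is the exact inverse of the forward map
$\phi = \theta/\psi$ with $\psi$ tied to $\theta$ through the quality link,
which the test suite verifies both symbolically (chained evaluation equals a
single expression) and statistically (generator truth is recovered).

Because estimation is restricted to households reporting positive cigarette
expenditure — the survey cannot distinguish true zeros from missing data —
all elasticities are *conditional* on smoking. No attempt is made to convert
them into total elasticities.

## Preprocessing conventions

* Quantities recorded in sticks are divided by the pack size (20 cigarettes
  per pack in Uganda) before unit values are formed.
* All monetary amounts are deflated to base-year prices with a user-supplied
  CPI series; internally everything is in base-year units. A helper converts
  annual recalls (divide by 52) and 30-day recalls (divide by 30/7) to
  weekly amounts; these factors are a convention, the estimator itself is
  recall-period agnostic.
* Education of the household head enters as $\ln(1 + \text{years})$ so heads
  with no schooling are retained; size and age enter in natural logs; the
  gender and employment dummies are 1 for male and employed.
* Records with positive expenditure but missing or non-positive quantity
  cannot yield a unit value and are dropped with a logged count, as are rows
  missing any regressor. Estimation is unweighted throughout.
* Both within equations are fit on the same household sample, so the
  residual covariance $\hat\sigma_{12}$ is well defined. In this conditional
  design $n_c^+ = n_c$; both counts are carried so the code generalises to
  designs that keep non-purchasing households in the share equation.
* Singleton clusters (common in sparse smoker samples) are retained: they
  are inert in the within stage — their demeaned rows are identically zero —
  but they contribute cluster averages to the between stage.

## The synthetic-survey generator

`simulate_survey()` draws, per cluster, $\ln \pi_c \sim N(0, \sigma_\pi^2)$
and $FE_c \sim N(0, \sigma_{fe}^2)$; per household, log expenditure
$N(\mu_{\ln x}, \sigma_{\ln x}^2)$, covariates from simple distributions
calibrated to the Uganda descriptive statistics (household size
$1+\mathrm{Pois}(4.6)$, proportions of adults and males from Beta
distributions with means 0.55 and 0.53, schooling $\mathrm{Pois}(6.5)$, age
$25+\Gamma(4,4)$, male-head and employed-head Bernoulli 0.87 and 0.89), and
jointly normal errors $(e, u)$ with SDs $\sigma_e, \sigma_u$ and correlation
$\rho_{eu}$. Log unit value and budget share then follow the two-equation
structure above, expenditure on the good is $w x$, and quantity is backed
out as expenditure over the unit value, optionally re-expressed in sticks
and/or rounded to whole sticks to emulate discretisation error.

Default parameters form a scenario shaped like the 2005 Uganda cigarette
sample: $\beta = 0.234$, $\varepsilon = -0.056$, mean share 8.86%, mean unit
value ≈ 1952 shillings/pack, mean weekly expenditure ≈ 34,598 shillings, and
price slopes $(\theta, \psi)$ solved by `solve_price_slopes()` so the
generating model's conditional price elasticity is exactly −0.326 *and* the
quality-correction chain inverts it exactly in the no-noise limit. The
dispersion parameters ($\sigma_{\ln x} = 0.35$, $\sigma_\pi = 0.3$,
$\sigma_{fe} = 0.015$, $\sigma_e = 0.3$, $\sigma_u = 0.012$,
$\rho_{eu} = 0.3$) are not published quantities; they were chosen so that
(i) spatial price variation is strong, (ii) measurement error is large
enough for the errors-in-variables correction to matter, and (iii) the
linear share model stays effectively exact — structural shares are clamped
into $(0.001, 0.999)$ with a logged count, and under the defaults well under
1% of draws are affected. Shares outside the unit interval are clamped, not
redrawn, to keep the interior model linear; scenarios that truncate more
than 10% of draws warn, and more than 50% is treated as a degenerate
configuration.

The generator emits smokers only, matching the conditional design; it does
not model participation, panel attrition, brand choice, or the joint
distribution of $(e, u)$ beyond a correlated normal — real recall error is
likely heavier-tailed and asymmetric. Passing parameter-recovery tests on
this generator therefore validates the estimator's algebra and its
error-correction logic, not the substantive correctness of any particular
survey's elasticity.

## Numerical and design choices

* **Fixed-effects estimator.** Demeaning plus `lm.fit`; the dummy-variable
  regression is used only as an independent oracle in tests. Rank
  deficiency after demeaning (e.g. a covariate constant within every
  cluster) raises an error naming the offending columns rather than
  silently dropping them.
* **Degrees of freedom.** Residual moments and reported SEs use
  $n - k - C$, the classical fixed-effects correction. Reported
  coefficient SEs are conventional homoskedastic OLS SEs; inference for the
  elasticities comes from the cluster bootstrap, not from those SEs.
* **Between-stage moments** use sample (C − 1) covariance/variance, for
  unbiasedness at small cluster counts. A corrected denominator at or below
  zero — the measurement-error correction overwhelming the price signal —
  raises an error advising more or larger clusters.
* **Degenerate denominators** in the recovery chain (magnitude below 1e-10)
  raise errors rather than returning huge elasticities.
* **Bootstrap.** The resampling unit is the cluster, since prices vary at
  cluster level; each drawn copy is relabelled as a distinct cluster.
  Percentile 95% intervals are the default (they allow the asymmetry seen
  in small samples); normal-approximation intervals sit behind a flag.
  Replicates that fail (typically a degenerate corrected denominator in
  small weak-signal resamples) are dropped and counted; above 5% the result
  is flagged unreliable. B defaults to 1000 and a seed is mandatory.
* **Trimming.** The robustness protocol computes mean and SD of raw unit
  values once, on the untrimmed estimation sample, and excludes households
  at or beyond $k$ SD (the boundary case is excluded). No iteration.
* **ANOVA.** The spatial-variation test runs on log unit values by default
  (the scale of the unit-value equation), with a switch for raw values for
  comparability with other studies. Degenerate partitions are reported
  explicitly (zero within-cluster variation gives $F = \infty$, $R^2 = 1$;
  a constant response gives $F = 0$).
* **Determinism.** Every stochastic component takes a seed and reruns are
  byte-identical, including the JSON report.

## Problem sizes used in the test suite

Parameter-recovery checks run at 500 clusters × 10 households with 100
Monte-Carlo replicates; ANOVA size calibration uses 500 seeds at 40 clusters
× 5 households; robustness and bootstrap-calibration checks use a few
hundred clusters and B of a few hundred. These sizes give Monte-Carlo
standard errors comfortably below the tolerances being asserted while
keeping the default suite fast.

## Known limitations

* Conditional elasticities only; the participation margin is out of scope.
* Single-good estimator; no cross-price effects or symmetry-restricted
  multi-good system.
* The Uganda samples behind the motivating application are restricted, so
  the published headline price elasticities (−0.326 in 2005, −0.258 in
  2009) are calibration anchors for synthetic scenarios, not reproduction
  targets; the desk-reproducible published quantities are the expenditure
  elasticities computed from printed coefficients, which the acceptance
  script recomputes.
* "Effective clusters" are defined here as clusters containing at least one
  household with positive cigarette expenditure; published counts based on
  an undefined alternative notion are not targeted.
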