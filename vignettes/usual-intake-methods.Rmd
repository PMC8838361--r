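---
title: "Estimating usual dietary intake from short recall windows: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating usual dietary intake from short recall windows: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usualintake)
```

## The problem

A person's *usual intake* of a dietary component — energy, a nutrient, a
food group — is their long-run average daily intake. It is the exposure of
interest in diet-disease epidemiology and the quantity against which intake
recommendations are judged. A 24-hour dietary recall (24-HR) measures a
single day, and a single day is a noisy measurement of the usual intake:
day-to-day (within-person) variation typically equals or exceeds
between-person variation, and episodically consumed foods (meats, eggs,
beans) contribute many days of exactly zero intake. The empirical
distribution of short-window person means is therefore *overdispersed*: its
mean is about right but its tails are far too wide, and naive prevalence
estimates of inadequate or excessive intake are badly biased.

This package implements and cross-validates three estimators of usual
intake from a short window of repeated recalls — here, three consecutive
recall days containing two weekdays and one weekend day — against a
reference standard built from many recall days:

* **the short-window mean** (the "3-day method"): each person's mean over
  their 1-3 available days, and the group distribution of those means;
* **an NCI-style two-part nonlinear mixed model**: consumption probability
  by mixed-effects logistic regression, consumption-day amounts by a
  Box-Cox-transformed linear mixed model, with optionally correlated
  person-level random effects; group distributions by Monte-Carlo
  pseudo-persons and individual estimates by the posterior mean of the
  model-implied usual intake given the person's observed days;
* **an MSM-style estimator**: per-person consumption probability from the
  same logistic machinery, per-person usual consumption-day amount by
  regression-residual shrinkage on a two-parameter Box-Cox scale, the
  individual usual intake as their product, and the group distribution read
  directly off the individual estimates.

The reference standard ("28-day truth") is each person's arithmetic mean
over all of their available recall days — four seasonal Monday-Sunday weeks
in the emulated design, 23-28 days per person after exclusions.

## The data-generating model and the synthetic cohort

The study the package emulates collected recalls from 752 Chinese adults,
but those data are non-public. All validation therefore runs on a synthetic
cohort whose generator implements exactly the structure the estimators
assume, with known ground truth:

For person $i$ with covariate vector $x$ (intercept, female indicator, age
standardised to mean 40 / SD 10 years, weekend indicator), random effects
$(u_{1i}, u_{2i})$ are bivariate normal with SDs $\sigma_{u1}, \sigma_{u2}$
and correlation $\rho$. On day $d$:

$$\Pr(\text{consume}) = \operatorname{logit}^{-1}(x_{id}'\beta_1 + u_{1i}), \qquad
g(a_{id}; \lambda) = x_{id}'\beta_2 + u_{2i} + \epsilon_{id},$$

with $\epsilon_{id} \sim N(0, \sigma_e^2)$ and $g$ the one-parameter
Box-Cox transform ($\log$ at $\lambda = 0$). Days are conditionally
independent given the random effects — the same assumption both estimation
methods make. Transformed-scale draws outside the Box-Cox support are
redrawn (rejection sampling, unbiased within the support); the rejection
rate is logged and a rate above 10% is treated as a spec error. The
analytic per-person usual intake is

$$T_i = \tfrac{5}{7}\,p(u_{1i}; \text{weekday})\,E[a \mid u_{2i}, \text{weekday}]
      + \tfrac{2}{7}\,p(u_{1i}; \text{weekend})\,E[a \mid u_{2i}, \text{weekend}],$$

averaged equally over seasons, with the residual expectation computed by
Gauss-Hermite quadrature on the back-transform (renormalised over the
support, matching the rejection sampling). Property tests confirm that
empirical per-person means converge to $T_i$ and that the pooled empirical
mean matches $\bar T$ to well under 1%.

### Calibration to published profiles

`calibrate_generator()` adjusts both intercepts and
$(\sigma_{u1}, \sigma_{u2}, \sigma_e)$ by a deterministic, damped
coordinate search until a large-sample simulation reproduces a target
profile: mean, CV, variance ratio (VR, within- over between-person daily
variance) and percentage of zero-intake days, at tolerances of ±2% on the
mean, ±5 CV points, ±20% on VR and ±3 percentage points on the zero share.
Two scale conventions matter here:

* Published descriptives of "true intake" tables are statistics of the
  *per-person multi-week means* (the usual-intake distribution), not of
  single days. This is forced by arithmetic: a component with ~42% zero
  days cannot have a daily-scale CV of 50% — Bernoulli switching alone
  pushes the daily CV above ~85% — while a person-mean CV of 50% is
  perfectly consistent. `describe_component()` therefore reports SD/CV and
  percentiles on the per-person-mean scale, and VR on the daily scale (its
  standard definition).
* For episodic components whose person-mean CV sits below the
  homogeneous-probability floor, the search raises $\sigma_{u1}$:
  polarising per-person consumption probabilities moves variance from the
  within- to the between-person side and (when $\rho > 0$) lowers the CV.
  This is why the published eggs/beans profiles are reachable at all.

The generator's defaults are the emulated study's conditions: 752 persons,
4 seasons × 7 consecutive days (Monday-Sunday), 50.3% female, age
39.9 ± 10.2 truncated to 18-60, and an energy-like component (no zero days,
person-mean CV ≈ 29%, VR ≈ 1.35, log-normal amounts). Weekend effects
default to +0.2 logits on consumption and +0.05 on the log amount scale;
sex/age amount effects (−0.22, −0.03 per age-SD) give women and older
adults realistically lower energy intake. Seasonal shifts default to zero.

### What the generator does *not* emulate

Real recalls feature misreporting, day-to-day autocorrelation within a
week, portion-size quantisation (eggs!), bounded physiological support, and
multivariate dependence across components. None of these are generated, so
passing tests demonstrate correctness of the estimators *under their own
assumptions*, not robustness to violations of them. One visible
consequence: the published energy-plausibility bounds (600-4200 kcal men,
400-3500 kcal women), designed to catch misreporting, flag legitimate
heavy-tail draws from the unbounded log-normal generator; the analysis
scripts demonstrate the filter but run the study on the complete synthetic
cohort.

## The NCI-style estimator

**Variant selection.** Components with fewer than 5% zero-intake days use
an amount-only model (consumption probability taken as 1). Otherwise the
two-part model is used, with correlated random effects if the Spearman
correlation between per-person consumption frequency and consumption-day
mean amount is significant at $\alpha = 0.05$, uncorrelated otherwise. The
frequency measure defaults to the share of consuming days (the count of
consuming recalls is available as an option; on the balanced windows used
here the two orderings coincide).

**Transform and fitting.** Amounts are pre-scaled so the positive-amount
median is 1 (numerical conditioning; inverted on output) and Box-Cox
transformed. $\lambda$ is profiled on a grid (−1 to 1, step 0.1) and
refined by golden-section search, maximising the marginal likelihood
*including the transform's log-Jacobian*. At fixed $\lambda$ the amount
part is an exact Gaussian linear mixed model, so the profile is computed by
maximum likelihood via `lme4::lmer`; the logistic part uses `lme4::glmer`
with 9-point adaptive quadrature. For the correlated variant, $\lambda$ is
profiled on the factorised ($\rho = 0$) likelihood — where it is exact and
cheap — and all remaining parameters $(\beta_1, \beta_2, \sigma_{u1},
\sigma_{u2}, \sigma_e, \rho)$ are then re-estimated jointly at that
$\lambda$ by maximising the two-part marginal likelihood, integrated over
$(u_1, u_2)$ by a 9×9 Gauss-Hermite product rule centred on the
random-effect prior. With windows of at most seven days per person the
posteriors stay close to the prior, so prior-centred quadrature is
accurate; the package's quadrature reproduces `lmer`'s exact Gaussian
likelihood on zero-free data (a dual-route test). $\rho$ is kept off the
boundary (|ρ| ≤ 0.99) through a scaled tanh parameterisation.

**Group distribution.** For each person's covariates, `n_pseudo`
random-effect pairs are drawn from the fitted distribution and converted to
usual intakes $T = \frac57 p_{wd} E_{wd} + \frac27 p_{we} E_{we}$ (the
5/7-2/7 calendar weights are the natural choice for Monday-Sunday recall
blocks). The residual expectation $E[a \mid u_2]$ uses Gauss-Hermite
quadrature on the back-transform with *support truncation*: out-of-support
nodes contribute the boundary amount 0. Truncation (rather than a
Taylor-series correction) was chosen because it is simple, non-negative by
construction, and testable — at $\lambda = 0$ there is no boundary and the
log-normal closed form must be reproduced to 0.1%, which the tests verify.
The pooled draws give the mean and the 1st-99th percentiles (all
percentiles in the package use the same convention: linear interpolation
between order statistics).

**Individual estimates.** $e_i = E[T(u_1, u_2) \mid \text{person's
observed days}]$, computed on a 15-node-per-dimension Gauss-Hermite grid
with posterior weights (prior × likelihood of the person's indicators and
amounts, normalised); the amount variant uses the exact conjugate-normal
posterior of $u_2$. Against brute-force importance-sampling posterior means
the quadrature is accurate to well under 1%.

## The MSM-style estimator

Part 1 gives each person a consumption probability $p_i$: the posterior
mean of the inverse-logit at the person's covariates (weekday/weekend
weighted), under the same fitted logistic mixed model machinery. The
default habitual-consumer assumption means no structural never-consumers:
$p_i > 0$ always, and a component with no zero days is treated as consumed
daily ($p_i = 1$). External consumption-probability input and the
"50% of non-consumers are habitual" option are out of scope.

Part 2 transforms consumption-day amounts with a *two-parameter* Box-Cox
$g(a) = ((a + c)^\lambda - 1)/\lambda$, choosing $(\lambda, c)$ on a grid
($\lambda$ −1..1 step 0.1; $c$ ∈ {0, 1%, 5%, 10%, 25%} of the median
positive amount) by a Shapiro-Francia-type normality score (correlation of
order statistics with normal quantiles). Transformed amounts are regressed
on the covariates by OLS; residuals are decomposed into between- and
within-person variances $(\sigma_b^2, \sigma_w^2)$ by a one-way
method-of-moments ANOVA (negative between-variance floored at zero), and
each person's mean residual is shrunk by the BLUP factor

$$c_i = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_w^2 / n_i},$$

which grows with the person's number of consumption days $n_i$ (a
$\sqrt{c_i}$ variant is available behind a flag). The person's usual
consumption-day amount back-transforms the covariate prediction plus
shrunken residual with a bias correction: Gauss-Hermite integration over
Gaussian noise of variance $\sigma_b^2 (1 - c_i) + \sigma_w^2$ — the
posterior uncertainty of the person effect plus the day-level residual
variance. This is the posterior-predictive variance, exact for the
$\lambda = 0$ closed form $a_i = \exp(\text{pred} + c_i \bar r_i + v_i/2)$;
the narrower choice $\sigma_w^2 (1 - c_i)$ was considered and rejected
because it provably underestimates the group mean (by 5-10% on log-normal
test cases), breaking the mean-agreement property that all methods should
reproduce the observed daily mean to ~2%. Finally $e_i = p_i a_i$, and the
group distribution is simply the mean and percentiles of $\{e_i\}$ — no
separate distribution-estimation step, which is the operational signature
of this method family.

## Validation metrics

* **Group level**: percentage difference
  $\text{Diff\%} = 100 (\text{estimate} - \text{truth}) / \text{truth}$
  applied statistic by statistic (mean, percentiles 1-99) against the
  truth distribution built from per-person reference-standard means with
  the same quantile convention. Truth is season-independent. Cells with
  non-positive truth are undefined and excluded. To remove seasonal
  effects, percentile grids are averaged rank-wise across the four seasons
  (a rank-wise mean of non-decreasing grids stays non-decreasing).
* **Individual level**: MAE $= \sum_i |e_i - t_i| / N$ over all matched
  persons, and MAPE $= 100 \sum_i |e_i - t_i| / t_i / N$ over persons with
  $t_i > 0$ (zero-truth persons are excluded and counted). Tables render
  two decimals, half away from zero; internal values keep full precision.

## Numerical choices and edge cases

* Quantiles: linear interpolation between order statistics, everywhere.
* Quadrature: 9 nodes per dimension for fitting, 15 for individual
  posteriors, 41 for generator-side expectations (each cheap relative to
  its accuracy requirement).
* Amount-model zeros: a near-daily component may still contain a few zero
  days; they are floored at half the smallest positive amount before the
  transform, and the count is logged on the fit.
* Degenerate inputs: single-person datasets, all-zero components and
  missing components raise typed errors; persons with no consumption days
  under the two-part models fall back to the population prediction with
  $\tilde r_i = 0$ (logged); an all-`TRUE` indicator vector switches part 1
  to the saturated daily case.
* $\lambda < 0$ back-transforms cap the amount just inside the support
  boundary instead of producing infinities.
* Reproducibility: every stochastic step takes an explicit seed; rerunning
  `run_study()` with the same seed reproduces the report byte for byte.

## Problem sizes

The shipped test suite and scripts choose sizes that keep each check sharp
but quick: parameter recovery at 500 persons × 7 days, correlated-model
recovery at 300 persons, brute-force oracles at 2×10⁵ draws for 20 persons,
bias-ordering over 10 replicate simulations of 150 persons, and the full
end-to-end study at the emulated scale of 752 persons × 28 days × 3
components × 4 seasons × 3 methods.

## Known limitations

* The MSM reference implementation is a web service whose exact shrinkage
  and back-transform formulas are not published; the forms here are stated
  assumptions validated by property tests (shrinkage direction, closed-form
  agreement, mean agreement), not by equivalence to the service.
* Fits are per-season; season is not a covariate within a window (windows
  span one season by design).
* No survey weights (the emulated study used none); a covariate-table hook
  is the natural extension point.
* Heteroscedastic residuals, FFQ-informed probability covariates and
  between-component correlation are out of scope.
* On idealised daily log-normal data the NCI- and MSM-style individual
  estimators are near-identical (both approximate the same posterior mean);
  the clear separations the real study reports for episodic components are
  reproduced qualitatively (e.g. MSM overestimating low percentiles of
  highly variable episodic foods), not to the digit.
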