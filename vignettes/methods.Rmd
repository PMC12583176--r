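---
title: "Synthetic control evaluation of healthcare resource misallocation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic control evaluation of healthcare resource misallocation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthscm)
```

## The scientific problem

The 2012 Sanming healthcare reform is a canonical quasi-natural experiment
for studying whether system-level reform can reduce the *misallocation of
medical resources* — the over-concentration of hospitals, beds and
physicians in some cities relative to a national benchmark. With a single
treated city and no possibility of randomization, the synthetic control
method (SCM) is the natural estimator: it builds a weighted combination of
untreated "donor" cities that mirrors the treated city's pre-reform
characteristics and uses that combination's post-reform trajectory as the
counterfactual.

This package implements the full evaluation pipeline: the outcome index,
the SCM estimator with nested weight optimization, in-space and in-time
placebo inference, robustness and mechanism re-estimation, and a
ground-truth panel generator. The original 204-city panel underlying the
published Sanming estimates is not publicly deposited, so the package's
estimators are validated on synthetic panels with known truth, while the
published tables are used for exact arithmetic self-consistency checks
(see `sanming_tables()`).

## The misallocation index

For city $i$ and year $t$, let $R_{it}$ be the sum of the city's three
normalized resource components (hospitals and health centers, hospital
beds, physicians). The outcome is

$$
M_{it} \;=\; \frac{\lvert R_{it} - \bar R_t\rvert}{\bar R_t},
\qquad \bar R_t = \frac1n \sum_i R_{it},
$$

the absolute relative deviation from the unweighted yearly national mean.
The index is dimensionless, nonnegative, and zero exactly at the national
average.

Two within-year normalization schemes are offered, because the choice is a
genuinely open design point: the source description says only
"normalizing and summing" and the published index level cannot
disambiguate the scheme without the raw data.

* `minmax` (default): each component is mapped to $[0,1]$ across cities
  within a year. Chosen as the default because it is the most common
  reading of "normalize" for bounded composite indices.
* `mean_ratio`: each component is divided by its yearly cross-city mean.
  This scheme is exactly invertible, which the synthetic data generator
  exploits (below).

Z-scoring is deliberately excluded: it forces the yearly mean of totals to
zero, making the index's denominator degenerate. Both schemes are
invariant to uniform positive rescaling of any single component, so
measurement units never matter. The national mean is unweighted — the
index definition carries no population weights — and a `per_capita` flag
(off by default, since the index is defined on counts) divides components
by population first.

## The estimator

Let $X_1 \in \mathbb R^k$ collect the treated unit's predictors — each
covariate aggregated by its pre-treatment mean, plus the outcome at
individual lag years — and $X_0$ the $k \times J$ donor matrix. The
canonical nine-predictor design of the Sanming evaluation uses five
covariates (secondary and tertiary industry shares of GDP, GDP level, GDP
growth rate, registered population) and the outcome at 2007–2010.

**Inner problem.** Given diagonal predictor importance $V$ (nonnegative,
summing to one), donor weights solve

$$
W^*(V) = \arg\min_{W \in \Delta^{J-1}}
  (X_1 - X_0 W)^\top V (X_1 - X_0 W) + \epsilon \lVert W\rVert^2 ,
$$

a convex quadratic program over the probability simplex. It is solved
exactly by an active-set method written for this structure: the working
set solves a small equality-constrained KKT system, dual feasibility is
checked on the full gradient, and each iteration costs $O(kJ)$ because
only the thin $k \times J$ matrix is ever formed. The ridge
$\epsilon = 10^{-9}$ makes the minimizer unique when several donor
combinations achieve the same loss (duplicate donors resolve to an even
split; a lone exact twin of the treated unit gets an indicator weight).
The solver is cross-checked in the test suite against two independent
oracles: an exhaustive $10^{-3}$-resolution simplex grid and an exact
support-enumeration solve via QR.

**Outer problem.** $V$ is chosen to minimize the pre-treatment outcome
MSPE of the implied synthetic control,
$\frac{1}{T_0}\lVert Z_1 - Z_0 W^*(V)\rVert^2$. Because differentiating
through the inner program is awkward, the search is derivative-free:
multi-start Nelder–Mead on softmax-parameterized simplex coordinates, with
the uniform $V$ plus `n_starts` Dirichlet(1) draws (default 20) as
starting points. Including the uniform start guarantees the fitted
pre-period MSPE never exceeds the uniform-$V$ baseline. The Dirichlet
starts are governed by `scm_control(seed=)` and drawn in a local RNG
scope, so fits are bit-reproducible and never disturb the caller's RNG.
Successive inner solves are warm-started from the previous active set;
since the ridge makes the inner solution unique, this affects speed only.

**Standardization.** Each predictor row is standardized to mean 0,
variance 1 across treated-plus-donors before optimization — without this,
$V$ would be unit-dependent (GDP in yuan would dwarf index lags) — and the
scaling is recorded so balance tables report raw units.

**Reporting conventions.** The gap path is `treated - synthetic` per
year. The mean post-treatment effect averages the gaps from the treatment
year (2012) through the end of the sample, matching the published
11-row table layout. Balance bias is
$(\text{synthetic} - \text{treated})/\text{treated} \times 100$, reported
to two decimals; a zero treated value makes the row undefined (`NA`).
Effects are always reported in index units; display scaling by 100 is an
explicit flag (`scale100`), because published robustness narratives mix
percent and index conventions.

## Placebo inference

*In-space*: each donor is refit as a pseudo-treated unit with the genuine
treated unit removed from its pool. Fits whose pre-treatment RMSPE exceeds
`cutoff_multiplier` times the treated unit's are excluded. The default
multiplier is 5 — the conventional filter — with arbitrarily lax values
(e.g. 700, which retains nearly all curves) available to mirror published
practice; "RMSE" in that practice is read as the pre-treatment RMSPE, the
standard filter. Tightening the multiplier can only shrink the included
set (a tested invariant). The test statistic is the post/pre RMSPE ratio.
Two summaries are reported:

* `pseudo_p`: the fraction of included placebo units whose ratio is at
  least the treated unit's (can be zero);
* `pseudo_p_rank`: the permutation form $(b+1)/(m+1)$ with the treated
  unit's own ratio appended, bounded below by $1/(m+1)$.

Both are labelled as extensions in output: placebo curves, not p-values,
are the published inferential object. A pseudo-treated unit with a zero
pre-RMSPE has an infinite ratio and is included. Individual placebo fit
failures are recorded and excluded; more than 50% failures aborts.

*In-time*: the fit is repeated with a backdated treatment year, using only
data up to the year before the true treatment year so genuine post-reform
observations cannot leak into the placebo. Lag predictors at or after the
fake year are dropped with a message. At least two pre-years are required;
the published analysis also backdated to 2008 (leaving a single pre-year),
which is reachable via `allow_short_pre = TRUE` and then forces the
uniform-$V$ fit, since the nested search has nothing to fit on one
pre-year.

## Robustness and mechanism scenarios

A `scenario()` bundles donor exclusions (directly or through a
unit-to-group lookup such as province membership), sample truncation, an
optional outcome swap to a mediator, and an expected effect direction.
`run_scenario()` subsets, imputes the mediator if it has gaps, refits, and
tags the fit; `compare_scenarios()` tabulates mean effects against the
baseline; `direction_check()` evaluates the sign of the mean post-period
gap and the share of post years agreeing with it. Published robustness
point estimates on the real panel are deliberately *not* targets — they
require the undeposited data — so the scenario machinery is validated by
identity (the empty scenario reproduces the baseline exactly) and
stability (dropping irrelevant noise donors moves the estimate by less
than 0.02 index units on generated panels).

Mediator series with leading gaps (insured-person counts are only
observed from 2011 on) are filled by `impute_linear()`: interior gaps by
linear interpolation between nearest observed neighbours, leading gaps by
extending the straight line through the first two observed points
backwards (interpolation proper is undefined at the boundary, so backward
extrapolation is the only line-consistent reading), trailing gaps
symmetrically. Extrapolated negatives are clipped to zero with a warning
for count-like roles, preserving auditability.

## The synthetic data generator

`simulate_panel()` emulates the study conditions: 204 units over
2007–2022, treatment in 2012, an interactive-fixed-effects outcome

$$
Y_{it} = \delta_t + \theta_t^\top Z_i + \lambda_t^\top \mu_i +
  \varepsilon_{it}, \qquad \varepsilon_{it} \sim N(0, \sigma^2),
$$

with two latent factors, five covariates in the evaluation's roles, and
idiosyncratic noise $\sigma = 0.02$ by default (roughly 5% of the index's
typical level, a realistic signal-to-noise for administrative city data).
Latent covariates and loadings are drawn from bounded (uniform,
unit-variance) distributions so emitted shares stay inside $[0,100]$ and
GDP/population stay positive; emitted covariates are *affine* in the
latents, so convex-hull membership survives the transformation. The
treated unit's latents are an exact convex combination of 3–6 donors by
default — SCM is only well-posed in the hull — with `treated_draw =
"iid"` (exchangeable units, the correct null for calibration studies) and
`"outside"` (poor-fit diagnostics) as alternatives. The null mode forces
a zero effect path.

The default effect path ramps from $-0.02$ to $-0.23$ with a mid-period
dip. This is a stylistic default so demonstration output lands on the
magnitude scale of published Sanming estimates; it is not a data-derived
quantity.

*Components mode* realizes the outcome as an exact misallocation index:
per year, unit totals are sign-balanced around the national mean by a
greedy signed partition (largest deviations first, each taking the sign
that shrinks the running sum, so the residual is bounded by the largest
single deviation), one designated balancing donor absorbs the residual,
and totals are split into three proportional component counts. Feeding
the emitted counts through `compute_misallocation(..., "mean_ratio")`
reproduces the outcome column to within $10^{-10}$, a tested identity.
The min-max scheme is not exactly invertible this way, which is one
reason both schemes are exposed. *Mechanism mode* adds two mediator
series driven by the same loadings (so the treated unit's mediator
counterfactual is also representable): government health expenditure with
a positive post-period ramp for the treated unit, insured persons with a
negative one and missing pre-2011 cells.

What the generator does *not* emulate: serial correlation in shocks,
covariate dynamics (covariates are constant over time), spatial
spillovers, and the heavy-tailed heterogeneity of real Chinese city data.
Passing tests therefore demonstrate correctness of the machinery under a
well-specified factor model, not robustness to every feature of real
panels.

## Numerical choices and problem sizes

* Inner QP: ridge $10^{-9}$; dual tolerance well below the ridge so ties
  resolve by minimum norm; active-set iterations capped at $100J$.
* Outer search: Nelder–Mead `reltol` $10^{-8}$, default `maxit` 250 and
  20 Dirichlet starts. Monte-Carlo validation loops use lighter settings
  (1–2 starts, 60–100 iterations), which empirically changes recovered
  effects at the third decimal or below while keeping hundreds of nested
  fits tractable; these are the package's chosen problem sizes for its
  validation studies: 100 seeds at the full 204-unit design for effect
  recovery, 200 null panels of 20 units for placebo calibration, 100
  seeds of 40-unit panels for mechanism direction rates.
* Degenerate inputs: zero-variance predictors, single donors, constant
  components within a year, dropped treated units, backdated years with
  too few pre-years, and unbalanced or duplicated panel rows are all hard
  errors naming the culprit.
* The panel is treated as 204 units = 1 treated + 203 donors throughout;
  source descriptions vary between "203" and "204 cities" depending on
  whether the treated unit is counted.

## Known limitations

* The nested $V$ search is a local, derivative-free heuristic; with 21
  starts it is reliable on the designs validated here but is not a global
  optimality guarantee.
* `pseudo_p` is a permutation-style diagnostic over a finite donor pool,
  not a confidence procedure; no conformal or bias-corrected variants are
  provided.
* The index is a deviation-from-mean measure; alternative misallocation
  formulations (TFP-style, Theil/Gini decompositions) are out of scope.
* Published headline estimates cannot be reproduced here because the
  underlying panel is not deposited; only their internal arithmetic is
  checked, exactly.

## A worked example

```{r example}
sim <- simulate_panel(sim_config(n_units = 40, seed = 7))
spec <- predictor_spec(
  covariates = c("sec_industry_share", "ter_industry_share", "gdp",
                 "gdp_growth", "population"),
  lag_years = 2007:2010)
fit <- synth_control(sim$panel, spec,
                     control = scm_control(n_starts = 5, seed = 1))
summary(fit)
c(truth = sim$truth$mean_effect, estimate = fit$mean_post_effect)
```

```{r placebo}
pl <- placebo_space(sim$panel, spec, cutoff_multiplier = 5,
                    control = scm_control(n_starts = 1, nm_maxit = 60),
                    treated_fit = fit)
pl
```
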