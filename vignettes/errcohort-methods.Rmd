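---
title: "Excess relative risk models for an occupational radiation cohort: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excess relative risk models for an occupational radiation cohort: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errcohort)
```

## The problem

Workers at early plutonium-production facilities accumulated substantial
protracted external gamma doses and, in some plants, internal doses from
inhaled plutonium. Estimating the cancer mortality risk per unit of
external dose in such a cohort requires three ingredients that this
package implements end to end:

1. **Person-time tabulation.** Each worker's follow-up is split over
   fixed strata (sex, period of hire, birth cohort, smoking, plant) and
   time-dependent strata (attained age, calendar period, duration of
   follow-up, migration, plutonium-monitoring status, lagged dose
   categories, surrogate categories), accumulating person-years, event
   counts and person-year-weighted covariate means per cell.
2. **Excess-relative-risk (ERR) Poisson regression.** Cell counts are
   modelled as Poisson with mean `py * exp(X %*% gamma) * (1 + ERR)`,
   where the log-linear term is the baseline rate and the ERR term
   carries the dose response. Inference uses likelihood-ratio tests and
   profile-likelihood confidence intervals.
3. **A synthetic-cohort generator** with the statistical structure such
   an analysis assumes, so that the full pipeline is testable — the real
   individual worker records are not public.

## The rate model

For a cell with covariates $(s, a, x)$ the death rate is

$$\lambda(s,a,x,d) = \lambda_0(s,a,x)\,\bigl[1 + \mathrm{ERR}(d)\bigr],$$

with a log-linear baseline in log attained age (a power law), sex,
smoking (ever/never/unknown), a linear birth-cohort trend, residence
status after migration and, when internal-exposure effects are in the
model, a monitoring-status indicator. The composite excess is

$$\mathrm{ERR} = \mathrm{ERR}_{ext} + I_{mon}\,\mathrm{ERR}_{int}
  + I_{unmon}\,\mathrm{ERR}_{pusur},$$

where $I_{mon}$/$I_{unmon}$ are time-dependent indicators of plutonium
monitoring: monitored person-time carries a linear ERR in lagged internal
liver dose, unmonitored person-time carries category-level excesses for
the ordinal plutonium-exposure surrogate (category 0 is the reference).
Monitoring could be triggered by suspected disease, so workers count as
unmonitored until two years after their first monitoring date, and the
baseline monitoring indicator absorbs the selection effect.

External dose-response shapes available: linear $\beta d$;
linear-quadratic $\beta_1 d + \beta_2 d^2$; pure quadratic; linear with
cell-killing $\beta_1 d e^{-\beta_2 d}$ (the response may flatten or
turn over at high dose); linear-threshold $\beta (d-c)^+$ with the
threshold profiled over a grid (the likelihood is not smooth in $c$);
and window sums $\sum_i \beta_i d(p_i)$ over time-since-exposure or
age-at-exposure windows. Modifiers on the linear slope: a female:male
ratio on the identity scale (so a negative ratio is representable when
the female ERR estimate is negative) and an attained-age power
$(a/60)^\alpha$.

## Doses, lags and windows

Annual badge-derived organ doses are given per calendar year; within a
year the dose is assumed to accrue uniformly (the historical record has
no finer resolution — an assumption, not an inference). The cumulative
dose function $D(t)$ is therefore piecewise linear, and the lagged
cumulative dose used as the risk covariate is $D(t - L)$ with a default
lag $L = 5$ years (alternatives 2, 10, 15, 20). The lag is applied to
the continuous cumulative-dose function rather than to calendar-year
blocks, which avoids artificial jumps at year boundaries.

Exposure windows partition the past by time since exposure $s = t - u$
(half-open windows between the cutpoints, e.g. $[5,10), [10,15),
[15,20), [20,\infty)$, with dose more recent than the first cutpoint
excluded) or by age at exposure. Window components are computed exactly
as differences of $D$, so they always sum to the corresponding
cumulative dose. Under uniform within-year accrual a dose year sitting
19–20 years before the time at risk belongs almost entirely to the
15–19 window; conventions that attribute whole dose-years to the start
of the calendar year would shift it to 20+. The continuous convention
was chosen for consistency with continuous lagging, and the unit tests
pin it against an independent day-level oracle.

Dose categories use boundaries 10, 25, 40, 100, 150, 250, 500, 1000,
1500, 2000, 3000 mGy (internal dose adds 5000), a zero-dose category,
and left-closed right-open bins, matching the half-open person-time
convention so a dose exactly on a boundary is assigned
deterministically.

## Person-year splitting

Dates are fractional calendar years at day resolution (1/365.25);
"December 31 of year y" is represented as `y + 1` under the half-open
`[entry, exit)` convention. Follow-up runs from hire to the earliest of
death, the administrative end (end of 2008), and the censoring rules for
migrants: migrants who left before the migration cutoff (end of 2003)
are censored at the cutoff — their vital status could be ascertained up
to then but not after — and later migrants are lost at their migration
date; never-migrants censor at their last known date.

The splitter cuts each follow-up interval at every boundary of every
active axis: birthdays at age-bin edges, calendar edges, duration
cutpoints, the migration date, monitoring switch dates, plant entries
(the surrogate category is the career maximum over workplaces entered so
far) and the exact times at which the lagged cumulative dose crosses a
category boundary — these can fall mid-year because $D(t-L)$ is
piecewise linear. Within a sub-interval every axis level is constant;
person-years are conserved exactly. Weighted means use the sub-interval
midpoint for age and calendar time and the exact time average for the
lagged doses (linear between break times, so the average is the endpoint
mean). A death is assigned to the final sub-interval, whose closure
contains the death time; a death exactly on a bin boundary thus belongs
to the stratum just ended, the one with positive person-time.

A deliberately naive day-stepping tabulator (`brute_force_tabulate()`)
is shipped as a reference implementation; because every time-dependent
axis is monotone over follow-up, each worker enters a given cell once
and daily assignment can misplace at most one day at each end of a
cell. The test suite verifies the splitter against it per cell and per
worker at that 2-day bound.

The birth-cohort labels leave the 1938 birth year unassigned between
"pre-1938" and "1939–42"; this implementation places 1938 in the first
bin (an interpretation, flagged here).

## Maximum likelihood and inference

The grouped-Poisson log-likelihood $\sum_c [e_c \log \mu_c - \mu_c]$ is
maximized by damped Newton iteration with the analytic gradient and
Hessian. When the observed Hessian is indefinite far from the optimum,
the expected (Fisher) information — negative semidefinite by
construction — provides the fallback ascent system, with
Levenberg-style ridging as a last resort; step-halving keeps every
iterate admissible ($1 + \mathrm{ERR} > 0$ on every cell). Convergence
requires gradient norm below 1e-6 with relative log-likelihood change
below 1e-8 (both configurable via `fit_control()`).

Two non-regular situations are recognized rather than fought:

* **Boundary maxima.** With sparse events the likelihood can increase
  monotonically as a slope approaches the admissibility edge
  $\beta \to -1/d_{max}$ (an event-free high-dose cell). The fitter
  detects that the ascent direction leaves the admissible set, stops,
  and flags the fit as a boundary optimum; profile intervals then
  report the edge as an open bound (rendered "<x"), which is how such
  results are conventionally displayed.
* **Divergent (separation-like) maxima.** When the few events of a rare
  outcome all sit at high dose, the slope estimate runs to infinity;
  the site-specific pipeline reports the failure for that site and
  continues.

Likelihood-ratio tests use the chi-square law with degrees of freedom
equal to the parameter difference; two-sided p-values come from the
upper tail. A rank-deficient alternative (e.g. a quadratic term that the
data cannot separate from the linear one) is flagged and reported with
statistic 0 and p = 1 rather than a spurious df. Profile-likelihood
confidence intervals re-maximize all other parameters at each trial
value and find the points where the profile drops by
$\chi^2_1(0.95)/2 = 1.921$; a non-monotone profile is flagged. The
window-heterogeneity test compares the window model against a
common-slope model fitted to the *summed* window dose, so the null is
nested exactly.

Attribution decomposes each cell's fitted deaths into background
$py\,\hat\lambda_0$ and one excess component per ERR term; with a free
intercept the background-plus-excess total equals the observed total
exactly (the intercept's score equation), which the tests assert.

## The synthetic-cohort generator

The generator emulates the cohort structure the analysis assumes:
~25% women; hire years 1948–1982 drawn with period weights proportional
to the published hire-period counts; six plant groups with published
relative sizes; era-declining annual external (colon) doses — lognormal
with mean `dose_scale * plant_factor * exp(-0.105 (year - 1948))` —
calibrated once so the cohort mean 5-year-lagged cumulative colon dose
at end of follow-up is about 354 mGy, the published cohort mean;
plutonium monitoring for ~40% of radiochemical/plutonium-plant workers
with internal liver-dose series; smoking, migration (with the post-2003
ascertainment loss) and sporadic loss to follow-up.

Mortality is simulated from two independent cause-specific hazards on a
piecewise-constant yearly grid: the cause of interest
(solid cancers outside the main plutonium-deposition organs) with
baseline rising as attained age to the fifth power, a female:male ratio
of 0.8, an ever/never-smoker ratio of 1.5, 15% lower rates after
migration, an optional monitored-worker excess, and a multiplicative
dose ERR with configurable true slope (default 0.16/Gy); and a
Gompertz-like competing hazard for all other deaths. The earliest event
wins; sites are assigned to cancer deaths from published sex-specific
site shares re-weighted by any site-specific true ERRs. The true
internal-dose slope defaults to 0 — the printed record reports the
internal effect as non-significant after monitoring adjustment and
gives no point estimate — and the birth-cohort trend defaults to 0 for
the same reason; both are configurable. Random streams are split
per-worker from the master seed, so cohorts are reproducible and
insensitive to generation order.

What the generator does **not** emulate: dosimetry measurement error
and badge-reconstruction uncertainty; neutron doses; accident-driven
acute exposures as a separate process; correlation between smoking,
alcohol and dose; cause-of-death misclassification; employment gaps
(follow-up is continuous from hire). Passing recovery tests therefore
demonstrates that the estimator chain is consistent and calibrated under
the assumed structure, not that it is robust to these real-data
features.

## Problem sizes and calibration experiments

The shipped experiments use sizes chosen to give informative Monte-Carlo
precision on a single core: parameter recovery and profile-CI coverage
use 100 replicate cohorts of n = 2,000 workers (the mean estimate is
compared to the truth within 3 Monte-Carlo standard errors; coverage
within 3 binomial standard errors of 95%); the Wilks null calibration
redraws cell counts from a fitted null model 400 times on one fixed
person-year table, which tests the LRT's null law directly at the
fitting-engine level; the splitter oracle comparison uses 50 random
workers at day resolution. The end-to-end demonstration cohort in the
acceptance script uses n = 10,000.

## Known limitations

* The generator's hazards are evaluated at yearly midpoints; for the
  age powers used here the discretization bias is well below
  Monte-Carlo noise, but extremely steep hazards would need a finer
  grid.
* Site-specific analyses with a handful of cases are fragile by nature;
  divergent fits are reported, not repaired.
* The encoded summary tables of the source cohort contain three internal
  arithmetic inconsistencies (a surrogate-category population total, a
  female site-count column, and a person-year total row); the
  consistency checker reports them as known discrepancies so they are
  visible but do not fail the suite.
* Dates as fractional years make day-level arithmetic simple but only
  approximate true calendar dates (1/365.25 days); all published
  analyses operate at annual resolution, so nothing finer is needed.
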