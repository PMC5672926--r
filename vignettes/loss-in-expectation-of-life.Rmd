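---
title: "Methods: relative survival, extrapolation and loss in expectation of life"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative survival, extrapolation and loss in expectation of life}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifelost)
```

## The problem

Five-year relative survival summarises cancer prognosis at one point in
follow-up. The measures this package computes instead take the whole of
remaining life into view: the **loss in expectation of life** (LEL) — the
difference between the remaining life expectancy of comparable people
without the cancer and that of the patients — the **proportion of life
lost** (PLL, the loss as a share of the cancer-free expectation), and the
**total life-years lost** by an annual diagnosis cohort. Computed
separately by deprivation quintile, they quantify how the life-time burden
of a cancer is distributed across socio-economic groups: the most deprived
usually have worse cancer survival, but also shorter background life
expectancy, and the two scales (absolute years, proportion) can rank
quintiles in opposite directions.

## Model

All-cause mortality of patients is decomposed as
\[ h(t \mid x) = h^*(t \mid x) + \lambda_E(t \mid x), \]
where \(h^*\) is the expected (background) rate from a population life
table matched on sex, single year of age, calendar year and deprivation
quintile, and \(\lambda_E\) is the excess rate attributable to the cancer.
The corresponding survival factorises as \(S(t) = S^*(t)\,R(t)\) with
\(R\) the relative (net) survival.

We model the **log cumulative excess hazard** with restricted cubic
splines (the flexible parametric / Royston–Parmar family):
\[
\eta(t \mid x) \;=\; s(\ln t;\gamma)
 + x_{dep}'\beta_{dep}
 + s_a(a)'\beta_{age}
 + (s_a(a) \otimes x_{dep})'\beta_{int}
 + \textstyle\sum_l s_l(\ln t;\delta_l)\,x_l ,
\]
so \(\Lambda_E(t\mid x) = e^{\eta}\), \(R(t \mid x) = \exp(-e^{\eta})\) and
\(\lambda_E = \Lambda_E \,(\partial \eta/\partial \ln t)/t\). Deprivation
enters through four dummies (quintile 1 = reference), age as a restricted
cubic spline centred at a reference age, their interaction proportionally,
and the final sum gives the deprivation dummies and age-spline columns
**time-dependent effects** — i.e. non-proportional excess hazards.  Each
time-dependent covariate carries a full spline in \(\ln t\) (its own linear
term plus curvature terms), the standard parameterisation of
time-dependent effects in this model family; with a \(K\)-knot spline that
is \(K-1\) columns per covariate.

Restricted cubic splines are linear beyond their boundary knots, so
\(\eta\) is linear in \(\ln t\) beyond the last knot. Extrapolating \(R\)
therefore behaves like a Weibull tail — and because the expected rate
dominates total mortality at long follow-up, extrapolating *relative*
rather than observed survival is the stable route to life-time summaries.
`tail_slope()` reports the fitted tail slope per covariate pattern;
predictions are only monotone under extrapolation when it is positive, so
it is surfaced rather than assumed.

### Period analysis

Estimation uses only person-time inside a recent calendar window
(default 2007.0–2014.0, i.e. through 31 December 2013), via delayed entry:
a patient diagnosed before the window enters the risk set at
\(t_0 = w_{start} - \text{diagnosis date}\). This weights the fit toward
current survival experience while patients diagnosed long ago still inform
the long-term shape, shortening the extrapolation actually needed. The
likelihood with event indicator \(d_i\) is
\[
\ell = \sum_i d_i \ln\!\big(h^*_i(t_i) + \lambda_E(t_i \mid x_i)\big)
 - \Lambda_E(t_i \mid x_i) + \Lambda_E(t_{0i} \mid x_i),
\]
dropping the parameter-free expected-hazard integral. \(h^*_i\) is looked
up at each subject's attained age and calendar year at exit, not averaged
over groups.

## Numerical choices

* **Knots.** Baseline: boundary knots at the extremes and interior knots
  at quantiles of the log event times, 5 df (6 knots) by default;
  time-dependent effects 3 df; age spline 3 df with boundary knots at the
  2nd/98th age percentiles. All are configurable; the defaults are the
  conventional ones for this model family.
* **Optimisation.** Two deterministic stages: a proportional-effects fit
  started from the exponential-equivalent closed form (log event rate,
  unit slope in \(\ln t\)), then the full model warm-started with
  time-dependent coefficients at zero.  Columns are rescaled to unit SD
  internally for conditioning; coefficients are reported on the raw basis
  scale, so predictions are invariant. Quasi-Newton iterations
  (`nlminb`), relative tolerance `1e-10`; a fit that fails both the
  optimiser's own test and a gradient-norm check refuses to return unless
  forced.
* **Negative-hazard guard.** Flexible splines can transiently push the
  fitted total hazard \(h^* + \lambda_E\) at an event time to zero or
  below during optimisation. Below a floor of `1e-10` the log is replaced
  by its C²-smooth second-order expansion, keeping the likelihood
  differentiable; violations remaining *at the optimum* are counted and
  reported in `summary()` rather than silently absorbed.
* **Life-table arithmetic is exact.** \(S^*\) and
  \(E^* = \int_0^\tau S^*\) are computed as piecewise-exponential
  products/integrals over the segments on which attained age and calendar
  year are constant (boundaries at every integer attained age and every
  1 January); no quadrature error enters from the life table. Attained
  ages beyond the table's oldest row reuse that row; calendar years beyond
  the last tabulated year reuse the last year (a constant-future
  assumption — the natural conservative default when the assumption
  actually used for published extrapolations is unstated; it is exposed as
  a property of the table, so sensitivity runs can supply tables extended
  differently).
* **Patient life expectancy.** \(E = \int_0^\tau S^* R\) uses
  Gauss–Legendre quadrature of order 15 *within each life-table segment*
  (\(R\) is smooth there), so the only approximation is polynomial
  quadrature of a smooth factor; doubling the order moves results by
  less than \(10^{-4}\) years in the test suite.
* **Horizon.** \(\tau\) defaults to attained age `age_cap + 21`
  (e.g. 120 for a table capped at 99), by which point \(S^*\approx 0\) for
  realistic rates; the *same* \(\tau\) is used for \(E^*\) and \(E\) so
  PLL is a true fraction. Predictions fix the diagnosis year at 2013.0 by
  default (the most recent cohort year), configurable.
* **Dates** are decimal years throughout (2007.0 = 1 January 2007);
  the life table is annual, so nothing finer than a day matters, and
  same-day deaths get one day (1/365.25 y) of follow-up so the likelihood
  sees a positive interval.

## Standardisation

Age-specific LEL/PLL are combined with weights reflecting the age
distribution of the reference-year (2013) diagnoses, per quintile
(**internal** standardisation), pooled over quintiles, or from a supplied
external scheme (e.g. International Cancer Survival Standard bands — the
band weights are user input, since several ICSS variants exist). Two
conventions exist for the proportional measure; the default reports the
weighted mean of age-specific PLL ratios, with the ratio of weighted means
\(\sum w\,\mathrm{LEL} / \sum w\,E^*\) available via
`pll = "ratio_of_means"` — the choice matters little when age mixes are
similar, and exposing both resolves the ambiguity transparently. An
alternative `average = "per-patient"` mode averages over every
reference-year patient's exact profile, which equals internal weighting at
full age resolution. Total life-years lost is, definitionally, the
reference-year count times the mean LEL, always computed from
full-precision means — presentation rounding never feeds back into totals
(multiplying a 2-dp printed mean by the count reproduces a printed total
only to ~0.1–0.5%, which is expected, and is what the bundled published
England 2013 table is used to check).

## The synthetic registry

Real national registry data cannot be redistributed, so the package ships
a generator whose world is rich enough to exercise every pipeline stage
and simple enough to integrate in closed form:

* background mortality: Gompertz–Makeham per quintile,
  \(h^*(a) = c + \alpha_g e^{\beta a}\), with a 2%/year improvement factor
  (\(\rho = 0.98\)) and a 0.8 female multiplier; the default
  \(\alpha\)-gradient makes quintile-5 rates about 1.55× quintile 1,
  a realistic deprivation gap;
* diagnoses 1998–2013, Poisson counts (mean 1250/quintile/year, ≈100k
  total), truncated-normal ages on [40, 95] with quintile means
  72.1–70.1 and SD 10.5, matching the age structure of a typical
  poor-prognosis (lung-like) male cancer cohort;
* excess hazard: Weibull \(\lambda_0 k t^{k-1} e^{\theta_{dep} +
  \theta_{age}(a-70)}\) with \(\lambda_0 = 0.35\), \(k = 0.75\),
  \(\theta_{dep} = 0.06 (g-1)\), \(\theta_{age} = 0.025\), optional cure
  fraction (default 0) — five-year net survival around 30% at the
  reference age, graded by quintile and age.

The default emulates a *single cancer–sex stratum* (males); models are
fitted per cancer and sex anyway, so one stratum exercises every code path
at half the cost, and the generator is fully parameterised where other
structures are wanted. Background death times are drawn from the *same*
life table handed to estimation, so expected-rate misspecification is zero
by construction and estimation error is isolated (feeding estimation a
different table is how robustness experiments are set up). On the log
cumulative scale the generating model is linear in \(\ln t\) and age with
proportional effects — inside the fitted model's span, including its
extrapolation, so recovery checks are meaningful end to end.

`compute_truth()` integrates the scenario's closed-form \(S^*\) and \(R\)
by plain trapezoid on a 0.001-year grid — an independent code path from
the estimators — and standardises true age-specific values with the
realised 2013 diagnosis weights, i.e. the same weights the pipeline uses,
so fitted-vs-truth comparisons measure estimation error, not weight
sampling noise.

What the generator does **not** emulate: registration delay and loss to
follow-up, cohort-projection mortality improvement, stage at diagnosis,
within-quintile frailty, seasonality, or any calibration to published
national figures. Passing recovery tests therefore demonstrates that the
estimation machinery is correct under the stated assumptions, not that
real-registry estimates would be unbiased.

## Problem sizes used in the checks

The bundled checks run a ≈100k-patient default scenario (full model,
46 parameters) for recovery, a ≈20k constant-hazard scenario against the
exponential closed form \(1/\mu - 1/(\mu+\lambda)\), and a ≈20k scenario
with equal net survival but deprivation-graded background mortality.

A note on the two trends, because the mechanism is easy to state loosely.
With *identical* net survival \(R\) and uniformly higher background
mortality in the deprived group, both measures favour the deprived group:
the least deprived lose more years (longer background expectancy, more to
lose) *and* a larger proportion — higher background mortality concentrates
the survival weight \(S^*(t)/\int S^*\) at early follow-up where \(R\) is
still high, so the survival-weighted mean of a non-increasing \(R\) can
only rise, and PLL \(= 1 - \int S^* R / \int S^*\) falls. That is the
pattern reported for cancers with similar net survival across quintiles
(ovarian-like). The trend *reversal* — years lost falling with deprivation
while the proportion rises, as seen for lung-like cancers — additionally
requires net survival to worsen with deprivation, which the default
scenario has (\(\theta_{dep} > 0\)); its quintile orderings of LEL and PLL
then move in opposite directions, and the recovery checks confirm the
fitted pipeline reproduces both orderings from data.

## Known limitations

* No confidence intervals for LEL/PLL are produced (the coefficient
  covariance is available; propagating it through the double integral is
  future work).
* No cure-fraction estimation, frailty, or Bayesian fitting.
* Ederer I / Hakulinen expected-survival variants are out of scope; the
  Ederer II-style attained-age/year lookup is used throughout.
* The constant-future life-table extension is an assumption; decades-long
  extrapolations inherit it.
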