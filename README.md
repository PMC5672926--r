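# lifelost

Quantifying the life-time impact of a cancer diagnosis by socio-economic
group: **loss in expectation of life (LEL)**, **proportion of life lost
(PLL)** and **total life-years lost**, estimated from cancer-registry data
with flexible parametric relative survival models.

Point-in-time metrics such as 5-year relative survival do not say how many
years of life a diagnosis actually costs. This package implements the
whole estimation chain used for that question in population-based cancer
epidemiology, for analysts working with registry records and national
life tables:

1. **Period analysis preparation** — a first-tumour filter and a
   left-truncated (delayed-entry) view of the registry restricted to a
   recent calendar window, so estimates reflect current survival.
2. **Flexible parametric relative survival model** — restricted cubic
   splines on the log cumulative excess hazard,
   `η(t|x) = s(ln t; γ) + x'β + Σ_l s_l(ln t; δ_l) x_l`,
   with a non-linear age effect, deprivation-quintile effects, an
   age x deprivation interaction, and time-dependent (non-proportional)
   effects; fitted by maximum likelihood with the expected hazard `h*`
   taken from a life table stratified by sex, single year of age,
   calendar year and deprivation quintile. Because the spline is linear
   in `ln t` beyond its boundary knots, relative survival
   `R(t|x) = exp(-exp(η))` extrapolates with a principled Weibull-like
   tail.
3. **Life-table arithmetic** — expected survival `S*(t)` and expected
   remaining life `E* = ∫ S* dt` computed *exactly* as
   piecewise-exponential products over attained-age/calendar-year
   segments, with documented age-cap and calendar-extension rules.
4. **Life expectancy and loss** — `E = ∫ S*(t) R(t|x) dt` by segment-wise
   Gauss-Legendre quadrature; `LEL = E* - E`, `PLL = LEL / E*`.
5. **Standardisation and totals** — internal (per-quintile 2013 age
   distribution), pooled, or user-supplied external weights (e.g. ICSS
   bands); `total life-years lost = N_2013 x mean LEL`.
6. **A synthetic registry generator** with Gompertz-Makeham background
   mortality, Weibull excess hazards and exact closed-form ground truth
   (`compute_truth()`), so the full pipeline is testable without any
   restricted data.

## Worked example

Simulate a lung-like male cohort (five deprivation quintiles, diagnoses
1998–2013), prepare the 2007–2013 period view, fit the model and estimate
the losses:

```r
library(lifelost)

sc  <- lel_scenario(seed = 2024, annual_mean = 400)
lt  <- make_life_table(sc)
reg <- simulate_registry(sc, lt)

pd  <- make_period_dataset(first_tumour_filter(reg))
pd
#> Period-analysis dataset: 20045 subjects, window [2007, 2014)
#>   events: 13176  delayed entry: 6029

fit <- relsurv_fpm(pd, lt)
fit
#> Flexible parametric relative survival model (log cumulative excess hazard)
#>   sex: M   n = 20045   events = 13176
#>   baseline df: 5  age df: 3  TD effects: 7
#>   log-likelihood: -26993.765  max|grad|: 0.00307  converged: TRUE

loss_in_expectation(fit, lt, patient_profile(70, "M", 5, 2013.0))
#> Profile: age 70.0, sex M, deprivation 5, diagnosed 2013.0
#>   E* (no cancer)    18.233 years
#>   E  (with cancer)   3.040 years
#>   LEL               15.193 years
#>   PLL                 83.3 %
#>   (horizon 50.0 y, GL order 15, tail slope 0.793)
```

A 70-year-old man in the most-deprived quintile could expect 18.2 more
years without the cancer but 3.0 with it: 15.2 years lost, 83% of his
expected remaining life. The positive tail slope confirms the
extrapolated relative survival is still decreasing.

Internally standardised averages and the annual-cohort burden, one row
per quintile:

```r
summary_table(list(lung = list(M = fit)), lt, first_tumour_filter(reg))
#>   cancer sex dep N_2013 mean_LEL mean_PLL total_years_lost
#> 1   lung   M   1    419    17.33   0.8004             7261
#> 2   lung   M   2    446    17.14   0.8106             7645
#> 3   lung   M   3    385    16.50   0.8142             6353
#> 4   lung   M   4    392    15.68   0.8262             6146
#> 5   lung   M   5    387    16.32   0.8244             6317
```

Mean years lost *fall* with deprivation (the least deprived have longer
background life expectancy — more years to lose) while the mean
*proportion* of life lost rises (net survival worsens with deprivation):
the two measures rank quintiles in opposite directions, which is exactly
why both are reported. `run_pipeline()` drives the same chain from a
single YAML/list config and writes CSV/JSON artifacts; `age_profile()`
gives the age-specific curves; `weight_scheme()` accepts external
standards such as ICSS bands.

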