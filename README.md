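# fertcurve

Parametric modelling of single-year age-specific fertility schedules.

The age-specific fertility rate (ASFR) f(x) gives births per woman per
year at each single year of age x over the reproductive span 15–49; its
sum is the total fertility rate (TFR). `fertcurve` is for demographers and
population scientists who want to summarise, smooth, compare and simulate
such schedules with parametric curves. It implements nine families — the
Hadwiger curve, the Peristera–Kostaki double Gaussian, the Gompertz
fertility curve, the Azzalini skew normal, the Gupta–Pasupuleti
beta-kernel curve, and four modified forms that add a late-age constant
(a, s), a scale exponent (γ), split pre-/post-peak spreads, or a shifted
support, e.g.

- modified P-K: f(x) = a + b·exp{−((x−μ)/σ₁)²} for x ≤ μ (σ₂ above),
- modified Gompertz: f(x) = (α/β)^γ · exp[−(x−m)/β − α·e^{−(x−m)/β}],
- modified G-P: f(x) = s + p·u^q·(1−u)^r with u = (x−15)/49,

fitted by bounded multi-start nonlinear least squares (`nlminb`), ranked
by small-sample corrected AIC computed from the SSE
(AIC = 2k + n·ln(SSE/(n−k)), AICc = AIC + 2k(k+1)/(n−k−1)), with
loess-style tricube local-polynomial smoothing, single-year ASFR
estimation from DHS-style birth histories (century-month codes, events
over month-by-month exposure in a 3-year retrospective window), seeded
synthetic data generators, and the published NFHS-4 (India 2015–16)
reference estimates for India and six states.

## Worked example

Generate a noisy India-like schedule, fit several families, and compare:

```r
library(fertcurve)

sched <- generate_schedule(
  "modified_gompertz", nfhs4_param_vector("modified_gompertz", "India"),
  noise = "gaussian", sd = 0.002, seed = 1
)
summarize_schedule(sched, region = "simulated India")
#> # A tibble: 1 × 5
#>   region            tfr peak_rate peak_age late_age_rate
#>   <chr>           <dbl>     <dbl>    <int>         <dbl>
#> 1 simulated India  2.19     0.197       22       0.00188

fits <- lapply(
  c("hadwiger", "gompertz", "modified_gompertz", "pk", "modified_pk"),
  function(f) fit_fertility_model(sched, f)
)
compare_models(fits, region = "simulated India")
#> # A tibble: 5 × 8
#>   region          family                k      sse   aic  aicc r_squared best
#>   <chr>           <chr>             <int>    <dbl> <dbl> <dbl>     <dbl> <lgl>
#> 1 simulated India modified_gompertz     4 0.000105 -433. -431.     0.999 TRUE
#> 2 simulated India modified_pk           5 0.000593 -369. -367.     0.996 FALSE
#> 3 simulated India pk                    4 0.000769 -363. -362.     0.995 FALSE
#> 4 simulated India hadwiger              3 0.00138  -346. -345.     0.991 FALSE
#> 5 simulated India gompertz              3 0.0691   -209. -208.     0.562 FALSE
```

The generating family wins on AICc: its four extra-flexible parameters
reduce the SSE by an order of magnitude over the Hadwiger curve and by
two orders over the plain Gompertz, whose fixed kurtosis cannot track a
right-skewed schedule. Derived summaries come from the fitted curve:

```r
best <- fits[[3]]
model_peak("modified_gompertz", best$params)
#> # A tibble: 1 × 3
#>   family            peak_age peak_rate
#>   <chr>                <dbl>     <dbl>
#> 1 modified_gompertz     22.5     0.198
model_implied_tfr("modified_gompertz", best$params)
#> [1] 2.192131
```

— a peak of 0.198 births per woman-year at age 22.5 and an implied TFR of
2.19, matching the schedule it was generated from. Fits are broom-friendly
(`tidy()`, `glance()`, `augment()`, `autoplot()`), and every step is also
available from a thin command-line wrapper,
`inst/cli/fertcurve.R` (subcommands `asfr`, `smooth`, `fit`, `compare`,
`simulate`, `simulate-schedule`, `interpret`, `checks`).

See `vignettes/fertility-curve-models.Rmd` for the models, estimation
details, identifiability caveats (the Gompertz family's exact parameter
ridge; δ in the modified skew normal) and the synthetic generator's
assumptions.

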