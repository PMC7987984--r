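---
title: "Parametric models for single-year fertility schedules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric models for single-year fertility schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertcurve)
```

## The problem

The age-specific fertility rate (ASFR) gives, for each single year of age
x in the reproductive span 15–49, the number of births per woman per year.
Fertility schedules in most populations are unimodal and right-skewed:
rates rise quickly from the mid-teens, peak somewhere between ages 19 and
24 at 0.14–0.23 births per woman-year, and decline slowly into the
forties. Summing the 35 single-year rates gives the total fertility rate
(TFR), the births a woman would have were current rates frozen.

Parametric curves compress a 35-point schedule into 3–5 interpretable
parameters, smooth the sampling noise and age-heaping of survey-based
single-year rates, and allow schedules to be compared, interpolated and
projected. `fertcurve` implements nine families — five classical and four
modified forms designed for schedules, like contemporary India's, that
retain a small but nonzero level of late-age (45–49) fertility:

| family | parameters | form |
|---|---|---|
| `hadwiger` | a, b, c | (ab/c)(c/x)^{3/2} exp{−b²(c/x + x/c − 2)} |
| `pk` | b, μ, σ₁, σ₂ | b·exp{−((x−μ)/σ_i)²}, σ₁ below the peak, σ₂ above |
| `modified_pk` | a, b, μ, σ₁, σ₂ | adds a late-age constant a |
| `gompertz` | α, β, m | (α/β) exp[−z − α e^{−z}], z = (x−m)/β |
| `modified_gompertz` | α, β, γ, m | scale exponent γ on (α/β) |
| `skew_normal` | λ, σ, δ | 2σ⁻¹ φ((x−λ)/σ) Φ(δ(x−λ)/σ) |
| `modified_skew_normal` | θ, λ, s₁, s₂, δ | θ exp(−½((x−λ)/s_i)²) Φ((δx−λ)/s_i) |
| `gp` | p, q, r | p x^q (1 − x/49)^r |
| `modified_gp` | p, q, r, s | s + p u^q (1−u)^r, u = (x−15)/49 |

The double-Gaussian (`pk`) exponent carries a negative sign: without it
the curve is unbounded and cannot represent a fertility schedule, and the
published parameter estimates for these models only reproduce plausible
curves under the bounded form.

In the modified skew normal the Φ argument is implemented as printed in
its defining equations, (δx − λ)/s rather than the conventional
δ(x − λ)/s. With published estimates (δ ≈ 1.5–3.5, λ ≈ 19–23) the two
readings give numerically indistinguishable curves because the argument is
far in the upper Gaussian tail at every age, but for small δ they differ;
`phi_arg = "centered"` switches to the conventional reading.

## Estimation

Fitting minimizes the sum of squared errors SSE = Σ_x (f(x) − f̂(x))² over
the schedule's ages with `nlminb()` (PORT, bounded quasi-Newton). Because
these objectives are multimodal and ridged, `fit_fertility_model()` is
multi-start:

* a deterministic data-driven start (`initialize_params()`): peak-shaped
  families start the level at the maximum observed rate, the location at
  its age, the pre-/post-peak spreads at 3 and 9 years (the asymmetry of
  observed schedules), and late-age constants at the mean 45–49 rate;
* `n_starts − 1` seeded jitters — multiplicative log-normal (sd 0.3) on
  positive parameters, additive ±3 years on locations (default seed
  20210323);
* for `modified_pk` and `modified_gompertz`, one start at the fitted base
  family extended with the neutral extra parameter (a = 0, γ = 1). Since
  the optimizer only descends, the modified family's SSE can never exceed
  its base family's — a guarantee the test suite asserts on arbitrary
  inputs.

Box constraints keep parameters in demographically meaningful ranges
(rates in (10⁻⁶, 1], late-age constants in [0, 0.05], locations in
[10, 49] years, spreads and α, β in (0.1, 30], γ in (0.1, 50], exponents
q, r in (0.01, 50], p in (10⁻⁶, 10⁶)). Asymptotic standard errors
(Gauss–Newton) are computed only behind `compute_se = TRUE`; by the
conventions of this literature they are not reported by default.

### Model selection

Fits are ranked by the small-sample corrected AIC computed from the SSE:

AIC = 2k + n·ln(SSE/(n−k)),  AICc = AIC + 2k(k+1)/(n−k−1).

The log's divisor is the residual degrees of freedom n−k, not n. This is
deliberate: the published NFHS-4 AICc values this package ships as
reference data reproduce only under that form, so adopting it keeps every
recomputation consistent. As n grows the correction vanishes and AICc
converges to AIC. `compare_models()` ranks ascending by AICc and, when two
fits are within 0.01 AICc units, prefers the one with fewer parameters —
an explicit parsimony tie-break for effectively indistinguishable fits.
R² is reported as 1 − SSE/TSS about the mean observed rate (a convention;
no universal definition exists for nonlinear fits).

### Identifiability

Two findings about these families matter when interpreting fitted
parameters, and they shape what the test suite asserts:

* **The Gompertz family is over-parameterized.** Rewriting the curve as
  C·e^{−x/β}·exp(−A·e^{−x/β}) with A = α·e^{m/β} and
  C = (α/β)^γ·e^{m/β} shows it depends on its 3 (or 4) parameters only
  through (β, A) and the scale C. α, γ and m individually lie on an exact
  ridge: noiseless data generated at published estimates are refit to
  SSE ≈ 10⁻³⁰ with γ 10% away from the generating value, while β, A and C
  are recovered to 14 significant digits. Derived quantities — the curve,
  its peak m + β·ln α, the implied TFR — are unaffected, but individual
  α/γ/m values should not be compared across sources.
* **δ in the modified skew normal is data-dependent weakly identified.**
  At published estimates the smallest Φ argument over ages 15–49 is about
  +6.5 standard deviations, so Φ ≡ 1 to below double precision and the
  SSE surface is flat in δ; perturbing δ by 5% moves the curve by less
  than 10⁻¹⁰. The remaining four parameters are recovered to machine
  precision from noiseless data.

## Smoothing

Single-year rates from survey microdata show single-age fluctuation and
digit preference. `smooth_schedule()` implements classical local
polynomial (loess-style) regression: at each age the ceil(span·n) nearest
ages are fit by a tricube-weighted polynomial (degree 2 by default) and
evaluated at that age. The default span of 0.2 — a 7-point local quadratic
for a 35-age schedule — removes single-age noise without flattening the
peak. The implementation is the textbook definition, verified against a
brute-force weighted-least-squares oracle to 10⁻¹⁰ at every point;
interpolation shortcuts of specific statistical packages are deliberately
not emulated. Models are fitted to the raw schedule by default —
smoothing before fitting changes the estimand, and the published fits are
equally consistent with either choice — with `fit_to = "smoothed"`
available.

## ASFR from birth histories

`compute_asfr()` estimates the schedule from DHS-style retrospective
birth histories (dates in century-month code, CMC = 12(year−1900)+month;
age in completed years). Over a window of `window_months` (default 36)
ending the month before the interview — the interview month itself is
excluded, matching the usual "3 years preceding the survey" convention —
each age's rate is weighted births to women of that completed age divided
by weighted woman-years of exposure, accumulated month by month (1/12
woman-year per month lived at that age inside the window). Sampling
weights are supported and default to 1. Ages with zero exposure return
rate 0 with a warning rather than an error, so small simulations still
yield complete schedules.

## The synthetic generator

`generate_schedule()` draws noisy schedules around any family's curve
(Gaussian sd 0.002 by default — the residual scale of survey-based
single-year schedules — truncated at zero, or binomial sampling with a
chosen number of women per age). `simulate_birth_histories()` emulates the
survey itself: interview ages uniform over 15–49 at month resolution, and
in each month of life from exact age 15 a birth with probability
f(completed age)/12, independently. The defaults emulate NFHS-4-like
conditions: unimodal right-skewed schedules with TFR around 1.6–2.8,
peak rates 0.14–0.23 at ages 19–24, small late-age fertility, and a fixed
interview month (CMC 1396, April 2016, the NFHS-4 fieldwork era).

Two deliberate simplifications: no 9-month refractory period between
births and no parity or marital-status structure. At rates below 0.25 per
woman-year the refractory constraint changes single-year ASFR by far less
than sampling error, and the memoryless hazard makes the events/exposure
oracle exact — simulated data are a test of estimation, not a demographic
microsimulation. Consequently, passing tests demonstrate the estimator
and fitting pipeline, not robustness to real-data features such as
displacement of birth dates, omission of dead children, or survey design
effects.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at sizes chosen to make
sampling error negligible relative to the assertions: one 200,000-woman
simulation for ASFR recovery (every age then has over 2,500 woman-years
of exposure, and estimates are asserted within 4 binomial standard errors
at ≥ 95% of ages), three 40,000-woman runs for the
simulate → estimate → fit → compare closure, and 20-start fits
elsewhere. Peak location uses a 0.001-year grid refined by golden-section
search, with ties broken toward the younger age; implied TFR is the
discrete sum over integer ages 15–49, matching how observed single-year
rates aggregate (for the Gompertz family it agrees with the analytic
integral β(α/β)^γ/α within 2%, the discretization plus truncation error).
Convergence uses `rel.tol = 10⁻¹⁴` with PORT's "singular convergence"
(flat Hessian, expected on the ridges above) accepted as converged.

## Reference values and their limits

The package ships the published NFHS-4 estimates (`nfhs4_parameters()`,
`nfhs4_fit_statistics()`, `nfhs4_region_summaries()`). Since the raw
NFHS-4 single-year schedules are not published, the original SSE/AICc
values cannot be recomputed from data; what is reproducible — and what
the test suite and `scripts/acceptance.R` recompute — are the derived
quantities of the published fits: implied TFRs (within ±0.05 of the
observed 2.2, 2.75 and 2.03 for India, Uttar Pradesh and Gujarat), peak
rates and ages, the AICc values implied by the published SSEs, and the
0.997 correlation between the Hadwiger scale parameter and observed TFR
across the seven regions. Five published AICc cells are internally
inconsistent with their own SSE beyond any rounding (flagged
`aicc_suspect`); correlations that require unpublished per-region
summaries (e.g. between late-age constants and observed late-age rates)
are not asserted anywhere.
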