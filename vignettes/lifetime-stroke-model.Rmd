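---
title: "A lifetime outcome model for stroke survivors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime outcome model for stroke survivors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokelifetime)
```

## The problem

Economic evaluations of acute stroke care need outcomes over a lifetime,
but trials observe patients for months. The usual fix — extrapolating a
dichotomized "independent vs dependent" outcome with ad-hoc mortality
assumptions — loses the granularity of the modified Rankin Scale (mRS)
and makes evaluations hard to compare. This package implements a set of
parametric risk equations that map three discharge covariates — age at
stroke onset, sex, and discharge mRS (0–5) — to lifetime mortality,
secondary-care resource use (emergency-department attendances,
non-elective and elective bed days), and from these to discounted
lifetime costs and QALYs.

## Model structure

**Mortality** uses two equations, because post-discharge mortality risk
is high in the first year, falls, and then rises again with age:

1. *Year 1*: a logistic regression for death within 12 months of
   discharge, on centered age, sex and mRS indicators (no interactions).
2. *Beyond year 1*: a Gompertz proportional-hazards equation
   $h(t) = \exp(\beta_0 + \beta' x)\, e^{\gamma t}$ on centered age,
   age², sex, mRS indicators and age×mRS interactions, fitted to
   survivors of year 1 with delayed entry at $t = 1$.

The probability of being alive $t$ years after discharge composes the
two: within year 1 the annual probability $p_1$ is spread at constant
hazard, $S(t) = (1-p_1)^t$; beyond it,
$S(t) = (1-p_1)\, S_G(t)/S_G(1)$. Lifespan is truncated at age 100 —
the national life tables carry no information beyond that age — so $S$
drops to zero at $t = 100 - \text{age}$ and any quantile that is not
reached is reported as the capped horizon with a flag. The constant
within-year-1 hazard is the minimal assumption consistent with a purely
annual first-year quantity; it changes nothing at integer years.

Because the derivation cohort is censored after a median of about six
years, the Gompertz equation cannot be estimated from the observed
deaths alone. Estimation is a two-stage life-table simulation:

* **Stage 1 (excess mortality).** Each replicate creates one synthetic
  general-population control per patient, matched exactly on age and
  sex, with a death time sampled from the national life table (hazard
  ratio 1). The combined stroke + control data are fitted by a Gompertz
  model with per-state indicators (controls as reference); coefficients
  are averaged over replicates, and the per-state hazard ratios versus
  the general population are the exponentials of the averaged state
  coefficients. Stroke deaths within year 1 are included, so these
  ratios summarize the *total* excess risk of each discharge state.
* **Stage 2 (completed lifetimes).** Each replicate gives every patient
  alive at censoring an imputed death age, sampled by walking the life
  table forward from their current age with their state's stage-1
  hazard ratio applied per year as $q' = 1-(1-q_x)^{hr}$ (exact under
  proportional hazards on the within-year scale), death placed
  uniformly within the death year, and forced within [100, 101) at the
  cap. The completed, fully-uncensored post-year-1 dataset is fitted by
  the Gompertz equation above; coefficients are averaged over
  replicates. Age² and age×mRS enter stage 2 always: the released model
  reports them in its final lifetime equation, so the package treats
  "include where fit improves" as settled rather than re-deciding per
  fit.

Replicate $r$ uses seed $\text{base} + r$, so both stages are
bit-reproducible. Replicates that fail to converge are dropped and
counted; more than 20% dropped is a hard error. The released model used
10,000 replicates; the package defaults to 200, at which doubling the
replicate count moves averaged coefficients by well under 1%.

**Resource use** treats each occurrence as a failure in a
counting-process (total time since discharge) formulation with delayed
entry: one failure per ED attendance day — unless the day falls inside
a non-elective stay, when the attendance is part of the admission and
suppressed — and one failure per occupied bed day, so a 15-day
admission is 15 sequential daily failures. Day-resolution data make
"at the same time" unambiguous only up to the day, and the
within-a-stay reading (any day in $[\text{start}, \text{start+length})$)
is adopted; same-day events are spread strictly inside their day so
stop times never tie. Follow-up for the resource processes ends at
death or administrative censoring, whichever is first (no joint
frailty model). The intensity families are Weibull for ED
($h(t) = p\,t^{p-1} e^{\beta'x}$) and log-logistic for both bed-day
streams, in accelerated-failure-time form
$S(t) = 1/(1+(t/e^{\beta' x})^{1/\gamma})$, whose "cumulative hazard"
$\Lambda(t) = \log(1 + (t/s)^{1/\gamma})$ is used as the operational
cumulative intensity — expected events to time $t$. All five families
(exponential, Weibull, logistic, log-logistic, Gompertz) can be ranked
by AIC ($2k - 2\ell$; ties broken by parsimony, then a fixed family
order, for determinism). The "logistic" entry of that menu has no
standard positive-support form; it is implemented here as a logistic
distribution on time left-truncated at zero so that $S(0)=1$ holds.

**Fitting** is censored maximum likelihood with delayed entry: row
$i$ contributes $h(t_{1i})^{d_i}\, S(t_{1i})/S(t_{0i})$. Positive
ancillary parameters are optimized on the log scale (the Gompertz
$\gamma$ is unrestricted), by BFGS with analytic gradients (numeric for
the truncated logistic), up to three deterministic restarts on
non-convergence, and standard errors from the inverted observed
information. The test suite cross-checks every family against an
independent implementation (`flexsurv`) on the same data, including
left-truncated fits.

**Economics.** Lifetime expected counts can be computed under two
conventions: the survival-weighted intensity integral
$E[N] = \int_0^H S(t)\,\lambda(t)\,dt$, or the cumulative intensity
evaluated at the median life expectancy, $\Lambda(\tilde t)$. The
published prediction grid is reproduced far more closely by the second
convention (calibration residuals below; the "matching life expectancy
with expected annual resource use" construction), so the packaged
reference bundle ships with `at_median` as its default and records the
choice in its metadata; both conventions remain available per call.
Costs and QALYs are continuous-time integrals weighted by survival and
discounted at rate $r$ (default 3.5%/year, the UK reference case, and
always explicit in the bundle):
$\text{cost} = \int S(t)\sum_r \lambda_r(t)\,c_r\,(1+r)^{-t}dt$,
$\text{QALY} = u(\text{state}) \int S(t)(1+r)^{-t}dt$. The default unit
costs are £137 per ED attendance, £533 per non-elective and £444 per
elective bed day. The per-state utility weights shipped as defaults
(0.97, 0.88, 0.74, 0.55, 0.20, −0.19 for mRS 0–5) are an *illustrative*
set from the utility-weighted-mRS literature, not the values used in
the original economic illustration, which were not redistributed;
substitute study-specific utilities for real evaluations.

## The reference coefficient bundle is calibrated, not transcribed

The original fitted coefficient tables are not redistributed with this
package. What is available are two published summary grids: survival
probabilities at years 1/3/5/10 plus median life expectancy for every
state and sex at the cohort mean age (73.69 years), and median survival
with lifetime resource use for ages 65/75/85 × both sexes × mRS 1/3/5.
`calibrate_reference_bundle()` reconstructs a coefficient set of the
stated functional form by weighted least squares against those grids
(residuals scaled by half the reproduction tolerances: 0.25 percentage
points for probabilities, 1% relative for times and counts), with
quantiles computed by root-finding inside the objective. The result,
shipped as `inst/extdata/reference_bundle_synthetic.json` and rebuilt
by `data-raw/make_reference_bundle.R`, is therefore a **synthetic
transcription stand-in**: faithful to the published *outputs*, not the
original fit. Resource levels for mRS 0, 2 and 4 — states the
prediction grid never covers — are interpolated linearly on the state
index and are the least-trustworthy part of the bundle.

Two findings from calibration are worth stating plainly:

* The published survival grid is *internally inconsistent with any
  single shared-shape Gompertz*: the mRS 0 row's own year-3/5/10
  ratios require $\gamma \lesssim 0.16$ (even allowing ±0.5 pp on every
  cell), while the mRS 4 row requires $\gamma \in [0.26, 0.34]$
  — and $\gamma$ does not vary with covariates in this model class.
  The likely cause is that the grid was produced by the original
  simulation pipeline rather than one coherent averaged equation. In
  consequence no parameter set can reproduce every survival cell to
  printed precision; the shipped bundle is the balanced compromise, and
  `validate_grid()` reports exactly which cells fall outside tolerance.
  The age-65/75/85 prediction-grid medians and all resource columns are
  reproduced to about ±2%; the survival-grid probabilities are
  reproduced to 1–3 percentage points, with the worst deviations where
  the grid conflicts with itself.
* The published interquartile ranges are similarly incoherent (one cell
  would need the hazard to jump roughly sevenfold within two months)
  and are excluded from the calibration objective.

## The synthetic cohort generator

`simulate_cohort()` draws discharge mRS from the derivation cohort's
distribution (139/333/366/359/268/44 over mRS 0–5), then age (truncated
normal) and sex from the per-state means, SDs and male fractions of its
baseline table, reproducing both the overall margins (mean age 73.69,
51% male) and the age/sex gradients across mRS. Administrative
censoring is uniform on 5.7–8.3 years (two years of discharges, one
censor date). Mortality follows the truth bundle's own two equations;
resource streams are inhomogeneous Poisson processes sampled exactly by
cumulative-intensity inversion, rounded to days, with consecutive bed
days grouped into stays. Two documented truths are provided:

* `default_truth()` emulates the derivation cohort, including its large
  first-year excess mortality (year-1 death probability ≈2% at mRS 0
  up to ≈56% at mRS 5 for a woman of mean age) and per-patient resource
  totals of the observed order (≈4 ED attendances, ≈23 non-elective
  and ≈1.2 elective bed days).
* `consistent_truth()` is the configuration for parameter-recovery
  validation: a pure-Gompertz synthetic life table (level 2.2e-5
  female / 3.2e-5 male at age 0, slope 0.095/year — chosen once to give
  plausible UK-like annual death probabilities), lifetime hazard equal
  to the life-table hazard times per-state ratios {1.2, 1.5, 2, 3, 5,
  10}, and a year-1 logistic fitted deterministically to the year-1
  death probabilities that same scaled hazard implies. Under this truth
  every quantity the pipeline estimates coincides with a generating
  parameter, so recovery can be tested without confounding from the
  first-year excess; with all ratios 1 it is the null configuration in
  which stage 1 should find no excess mortality.

What the generator deliberately does *not* emulate: comorbidity
covariates (not inputs to any equation), attribution of admissions to
stroke versus other causes, recurrent stroke as a distinct process,
within-day event timing, and any dependence between the resource
streams beyond their shared covariates. Passing recovery tests
therefore shows the estimation machinery is correct under the model's
own assumptions — not that the model is correct for real cohorts.

## Numerical choices

* Time unit: years since discharge; days convert at 365.25.
* Age centered at 73.69 years, so the base case (female, mean age,
  mRS 0) is the intercept alone.
* Quantiles of composed curves by bracketed root-finding (`uniroot`,
  tolerance 1e-9); family quantiles in closed form.
* Lifetime integrals by adaptive quadrature split at the year-1 kink
  (relative tolerance 1e-8); during calibration, where the survival
  curve is fixed, by a trapezoid rule on a 0.05-year grid with the
  first step's cumulative intensity taken exactly (the Weibull
  intensity is singular at $t=0$ when $p<1$).
* Gompertz kernels use `expm1` with series fallbacks below
  $|\gamma| < 10^{-10}$, so the exponential limit is smooth.
* Degenerate inputs are errors, not silent results: all-censored
  tables, unconverged fits used for prediction, profiles outside the
  life-table support, separation in the year-1 logistic (named state
  cell), mixing six-state profiles with a dichotomized bundle.

## Problem sizes used by the validation suite

The packaged validation runs at reduced but adequate scale, chosen so
that Monte-Carlo error stays well inside the tolerances being checked:
parameter recovery on a 5,000-patient cohort with 200 replicates per
simulation stage; the null (no-excess) check on 3,000 patients with 100
replicates; AIC family-selection consistency at n = 2,000 × 100
replicates per family; oracle equivalences on closed-form cases. The
fitting function itself has no scale ceiling beyond runtime.

## Known limitations

* The reference bundle inherits every limitation of calibration from
  published summaries (see above); where it disagrees with the original
  supplementary coefficients, the originals are authoritative.
* Stage-1 hazard ratios for rare states (mRS 0 has 139 patients and few
  late deaths in a derivation-sized cohort) carry sampling error of
  order 10–15% that no amount of simulation replication removes.
* The dichotomized variant produced by `dichotomize_model()` is a
  weighted collapse of the six-state equations, not a re-estimated
  model; fitting with `stroke_lifetime(..., dichotomize = TRUE)`
  estimates the binary equations directly.
* Costs cover secondary care only; primary, social and informal care
  are outside the model's data.

## A worked example

```{r example, eval = FALSE}
lt <- synthetic_life_table()
cohort <- simulate_cohort(n = 1509, seed = 1)
fit <- stroke_lifetime(cohort, lt, n_sims = 50, seed = 1)
print(fit)

# predictions from the packaged calibrated bundle
ref <- reference_model()
predict(ref, data.frame(age = 65, sex = "female", mrs = c(1, 3)))
compare_profiles(ref,
  data.frame(age = 65, sex = "female", mrs = 1),
  data.frame(age = 65, sex = "female", mrs = 3))$delta

# how well the calibrated bundle reproduces the published grids
print(validate_grid(ref))
```
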