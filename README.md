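# strokelifetime

Lifetime mortality and secondary-care use predictions for patients
discharged from hospital after acute stroke.

Health-economic evaluations of stroke interventions need lifetime
outcomes, but cohorts are observed for a few years at most. This package
implements a set of parametric risk equations that take the three
covariates routinely available at discharge — **age at stroke onset,
sex, and modified Rankin Scale (mRS 0–5)** — and return the quantities
an economic model needs over the remaining lifetime: a survival curve,
median life expectancy, expected emergency-department attendances and
elective/non-elective bed days, and discounted lifetime costs and QALYs.

The model's core, in the field's standard notation:

* death within 12 months of discharge: logistic,
  `logit p1 = β0 + βa(age−73.69) + βm·male + βmrs(k)`;
* death beyond 12 months: Gompertz proportional hazards,
  `h(t) = exp(xβ)·e^(γt)` with `x` = centered age, age², sex, mRS
  indicators and age×mRS interactions, estimated by a two-stage
  life-table simulation (synthetic matched population controls give
  per-state excess-mortality hazard ratios; those ratios impute death
  dates for patients alive at censoring; the completed data give the
  lifetime equation). Lifespan is truncated at age 100;
* composed survival `S(t) = (1−p1)^t` for `t ≤ 1`, then
  `(1−p1)·S_G(t)/S_G(1)`;
* resource use as recurrent events on the counting-process scale (each
  attendance or occupied bed day is a "failure" with delayed entry):
  Weibull intensity for ED, log-logistic for bed days, with expected
  lifetime counts either as `∫ S(t)λ(t)dt` or `Λ(median survival)`;
* family choice by AIC among exponential, Weibull, logistic,
  log-logistic and Gompertz.

The estimation pipeline (`stroke_lifetime()`), a synthetic cohort
generator with known ground truth (`simulate_cohort()`), life-table
machinery, a JSON coefficient-bundle interchange format, and a
prediction engine are all included. The vignette
(`vignettes/lifetime-stroke-model.Rmd`) documents the methods, the
numerical choices, and the calibration of the packaged reference
coefficients.

## Worked example

```r
library(strokelifetime)

ref <- reference_model()   # packaged calibrated coefficient bundle
predict(ref, data.frame(age = 65, sex = "female", mrs = c(1, 3)))
#>   age    sex state year1_death median_le le_q25 le_q75 le_capped   ed
#> 1  65 female     1      0.0422     15.77  11.73   18.9     FALSE 8.79
#> 2  65 female     3      0.0696      9.08   5.59   12.0     FALSE 8.95
#>   nonelective_days elective_days  cost qalys life_expectancy
#> 1             25.2          2.72 12995  9.89           14.77
#> 2             27.4          1.46 14161  3.99            8.68
```

A 65-year-old woman discharged with mRS 1 is predicted to live a median
15.8 years (IQR 11.7–18.9) and use about 8.8 ED attendances and 25
non-elective bed days over her lifetime; at mRS 3 the median falls to
9.1 years. The difference between the rows — 6.69 life years, slightly
fewer ED attendances and non-elective bed days at mRS 1, but 1.26 more
elective bed days — is the model's statement of what improving
discharge outcome is worth, before any costs outside secondary care:

```r
compare_profiles(ref,
  data.frame(age = 65, sex = "female", mrs = 1),
  data.frame(age = 65, sex = "female", mrs = 3))$delta
#>              age      year1_death        median_le           le_q25
#>            0.000           -0.027            6.687            6.145
#>           le_q75               ed nonelective_days    elective_days
#>            6.885           -0.162           -2.195            1.260
#>             cost            qalys  life_expectancy
#>        -1166.579            5.893            6.092

# fit the whole model from (synthetic) patient-level data
lt  <- synthetic_life_table()
coh <- simulate_cohort(n = 1509, seed = 1)
fit <- stroke_lifetime(coh, lt, n_sims = 200, seed = 1)
summary(fit)
plot(fit)                      # survival curves by discharge mRS
write_bundle(fit, "fit.json")  # interchangeable coefficient bundle
```

A thin command-line front end over the same functions ships at
`inst/cli/strokelife.R` (`fit`, `predict`, `compare`, `simulate`,
`validate`).

## About the packaged reference coefficients

The original fitted coefficient tables are not redistributed. The
packaged bundle (`inst/extdata/reference_bundle_synthetic.json`) was
**calibrated by least squares so that this package's prediction engine
reproduces the published summary grids** (survival probabilities and
median life expectancies by state and sex; medians and lifetime
resource use by age, sex and state). It is labelled synthetic in its
metadata; `validate_grid(reference_model())` prints exactly how close
each cell is, and the vignette explains why a handful of survival-grid
cells cannot be reproduced by any coefficient set of the stated model
form. For mRS 0, 2 and 4 the resource equations interpolate between
published states.

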