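#' Fit the lifetime stroke outcome model
#'
#' The main fitting function. Runs the full estimation pipeline on a
#' patient-level cohort and a national life table:
#'
#' 1. logistic regression for death within 12 months of discharge
#'    ([fit_year1()]);
#' 2. first-stage simulation against synthetic general-population controls,
#'    yielding per-state hazard ratios of death ([stage1()]);
#' 3. second-stage simulation imputing death dates for patients alive at
#'    censoring, yielding the lifetime Gompertz equation ([stage2()]);
#' 4. counting-process fits of the three resource equations
#'    ([expand_events()] + [fit_resource()]): Weibull for ED attendances,
#'    log-logistic for non-elective and elective bed days.
#'
#' Replicate `r` of either simulation stage uses seed `seed + r`, so a
#' fit is bit-reproducible given `(cohort, life_table, n_sims, seed)`.
#'
#' @param cohort a `"stroke_cohort"` (see [as_stroke_cohort()]).
#' @param life_table a `"life_table"`.
#' @param n_sims simulation replicates per stage (the released model used
#'   10,000; 200 gives coefficients stable to well under 1%).
#' @param seed base random seed.
#' @param dichotomize estimate the binary independent/dependent variant
#'   instead of the six mRS states.
#' @param centering_mean age-centering constant (years).
#' @param economics economic parameters (see [default_economics()]).
#' @param lifetime_count_method default convention for lifetime resource
#'   counts (see [lifetime_resource_use()]).
#' @param select_resources if `TRUE`, re-select each resource family by
#'   AIC among all five instead of using the released families.
#' @return a `"stroke_lifetime"` model; the underlying fits are kept in
#'   `$fits` and the AIC tables (when `select_resources`) in
#'   `$fits$resource_aic`.
#' @examples
#' \donttest{
#' lt <- synthetic_life_table()
#' coh <- simulate_cohort(n = 400, seed = 1)
#' m <- stroke_lifetime(coh, lt, n_sims = 10, seed = 1)
#' predict(m, data.frame(age = 65, sex = "female", mrs = 1))
#' }
#' @export
stroke_lifetime <- function(cohort, life_table, n_sims = 200, seed = 1,
                            dichotomize = FALSE, centering_mean = 73.69,
                            economics = NULL,
                            lifetime_count_method = "integral",
                            select_resources = FALSE) {
  stopifnot(inherits(cohort, "stroke_cohort"), inherits(life_table, "life_table"))
  states <- if (dichotomize) DICHOT_STATES else MRS_STATES

  y1 <- fit_year1(cohort, centering_mean, dichotomize)
  s1 <- stage1(cohort, life_table, n_sims, seed, centering_mean, dichotomize)
  s2 <- stage2(cohort, s1$hr, life_table, n_sims, seed + n_sims,
    centering_mean, dichotomize)

  released <- c(ed = "weibull", nonelective = "loglogistic", elective = "loglogistic")
  streams <- c(ed = "ed", nonelective = "nonelective_bed_days",
    elective = "elective_bed_days")
  rfits <- list()
  raic <- list()
  for (nm in names(streams)) {
    ev <- expand_events(cohort, streams[[nm]], centering_mean)
    if (select_resources) {
      tab <- compare_resource_families(ev, dichotomize = dichotomize)
      raic[[nm]] <- tab
      rfits[[nm]] <- attr(tab, "best")
      names(rfits[[nm]]$coefficients)[1] <- "intercept"
    } else {
      rfits[[nm]] <- fit_resource(ev, released[[nm]], dichotomize)
    }
  }

  mort <- list(
    year1 = list(coefficients = y1$coefficients),
    lifetime = list(family = "gompertz", coefficients = s2$coefficients,
      shape = s2$gamma),
    stage1_hr = s1$hr,
    sim_meta = list(n_sims = n_sims, seed = seed, truncation_age = 100)
  )
  res <- lapply(rfits, as_equation)
  new_stroke_lifetime(
    mortality = mort, resources = res,
    economics = economics %||% default_economics(states),
    states = states, centering_mean = centering_mean,
    lifetime_count_method = lifetime_count_method,
    fits = list(year1 = y1, stage1 = s1, stage2 = s2, resources = rfits,
      resource_aic = if (length(raic)) raic),
    metadata = list(
      n_patients = nrow(cohort), n_sims = n_sims, seed = seed,
      fitted = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
    )
  )
}

## parsurv fit -> bundle equation
as_equation <- function(fit) {
  co <- fit$coefficients
  names(co)[names(co) == "(Intercept)"] <- "intercept"
  list(family = fit$family, coefficients = co, shape = fit$shape)
}

#' Simulate cohorts from a fitted model
#'
#' Uses the model's own equations as the ground truth of the synthetic
#' cohort generator (see [simulate_cohort()]).
#'
#' @param object a `"stroke_lifetime"` object.
#' @param nsim number of cohorts.
#' @param seed base seed (cohort `i` uses `seed + i - 1`).
#' @param n patients per cohort.
#' @param ... passed to [simulate_cohort()].
#' @return a list of `"stroke_cohort"` objects (a single cohort when
#'   `nsim = 1`).
#' @export
simulate.stroke_lifetime <- function(object, nsim = 1, seed = 1, n = 1509, ...) {
  out <- lapply(seq_len(nsim), function(i) {
    simulate_cohort(n = n, truth = object, seed = seed + i - 1, ...)
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
residuals.stroke_lifetime <- function(object, ...) {
  stop("the multi-equation lifetime model has no single residual type; ",
    "inspect the component fits in $fits instead")
}
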