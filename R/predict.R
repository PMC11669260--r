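#' Composed lifetime survival for one covariate profile
#'
#' The probability of being alive `t` years after discharge composes the
#' two mortality equations: death within year 1 follows the logistic
#' equation (spread over the year at constant hazard, so
#' `S(t) = (1 - p1)^t` for `t <= 1`), and survival beyond year 1 follows
#' the conditional lifetime Gompertz,
#' `S(t) = (1 - p1) * S_G(t) / S_G(1)`. Lifespan is truncated at age 100:
#' `S` drops to 0 at `t = 100 - age`.
#'
#' @param model a `"stroke_lifetime"` object.
#' @param profile single-row data frame with `age`, `sex`, `mrs` (or
#'   `state`).
#' @return a vectorized function of time (years since discharge).
#' @export
survival_function <- function(model, profile) {
  profile <- check_profile(model, profile)
  stopifnot(nrow(profile) == 1)
  p1 <- year1_death_prob(model, profile)
  lt <- model$mortality$lifetime
  lp <- eval_lp(lt, profile, model$centering_mean, model$states)
  H <- model$truncation_age - profile$age
  sg1 <- family_surv(lt$family, 1, lp, lt$shape)
  function(t) {
    s <- ifelse(t <= 1,
      (1 - p1)^pmax(t, 0),
      (1 - p1) * family_surv(lt$family, pmax(t, 1), lp, lt$shape) / sg1
    )
    s[t >= H] <- 0
    s[t <= 0] <- 1
    s
  }
}

#' Survival curve on a time grid
#'
#' @inheritParams survival_function
#' @param grid_step grid resolution in years (`> 0`).
#' @return data frame with columns `time` and `surv`.
#' @export
survival_curve <- function(model, profile, grid_step = 0.1) {
  if (grid_step <= 0) stop("grid_step must be positive")
  profile <- check_profile(model, profile)
  H <- model$truncation_age - profile$age[1]
  if (H <= 0) stop("profile age is at or beyond the age-100 horizon")
  S <- survival_function(model, profile)
  grid <- unique(c(seq(0, H, by = grid_step), H))
  data.frame(time = grid, surv = S(grid))
}

#' Median life expectancy (with interquartile range)
#'
#' The time at which the composed survival probability reaches 0.5 (and
#' 0.25 / 0.75 for the interquartile range), found by bracketed
#' root-finding on the composed curve. When the curve never reaches the
#' level before the age-100 horizon the horizon is returned and flagged.
#'
#' @inheritParams survival_function
#' @return list with `median`, `q25`, `q75` (years) and logical `capped`
#'   (per quantile).
#' @export
median_le <- function(model, profile) {
  profile <- check_profile(model, profile)
  S <- survival_function(model, profile)
  H <- model$truncation_age - profile$age[1]
  if (H <= 0) stop("profile age is at or beyond the age-100 horizon")
  solve_level <- function(level) {
    if (S(H - 1e-9) > level) {
      return(c(t = H, capped = 1))
    }
    r <- stats::uniroot(function(t) S(t) - level,
      lower = 0, upper = H - 1e-9, tol = 1e-9)
    c(t = r$root, capped = 0)
  }
  med <- solve_level(0.5)
  q75s <- solve_level(0.75) # survival 0.75 -> 25th percentile of lifetime
  q25s <- solve_level(0.25)
  list(
    median = unname(med["t"]), q25 = unname(q75s["t"]), q75 = unname(q25s["t"]),
    capped = c(median = unname(med["capped"]) == 1,
      q25 = unname(q75s["capped"]) == 1,
      q75 = unname(q25s["capped"]) == 1)
  )
}

## Resource intensity lambda(t | profile) for one resource equation.
resource_intensity <- function(model, resource, profile) {
  eq <- model$resources[[resource]]
  lp <- eval_lp(eq, profile, model$centering_mean, model$states)
  function(t) family_hazard(eq$family, t, lp, eq$shape)
}

resource_cumintensity <- function(model, resource, profile) {
  eq <- model$resources[[resource]]
  lp <- eval_lp(eq, profile, model$centering_mean, model$states)
  function(t) family_cumhaz(eq$family, t, lp, eq$shape)
}

## Survival-weighted integral of f(t) * S(t) * extra(t) over [0, H],
## split at the year-1 kink.
surv_weighted_integral <- function(S, f, H, rel.tol = 1e-8) {
  intg <- function(lo, hi) {
    if (hi - lo < 1e-12) return(0)
    stats::integrate(function(t) S(t) * f(t), lo, hi,
      rel.tol = rel.tol, abs.tol = 1e-10, stop.on.error = TRUE)$value
  }
  if (H > 1) intg(0, 1) + intg(1, H) else intg(0, H)
}

#' Expected lifetime secondary-care resource use
#'
#' Expected number of events up to the age-100 horizon for each resource
#' stream. Two conventions are supported: `"integral"` accumulates the
#' resource intensity weighted by the probability of being alive,
#' `E[N] = integral of S(t | x) * lambda(t | x) dt`; `"at_median"`
#' evaluates the cumulative intensity at the median life expectancy,
#' `Lambda(median | x)`. The shipped reference bundle records which
#' convention its calibration selected; `method = NULL` uses the model's
#' own default.
#'
#' @inheritParams survival_function
#' @param method `NULL`, `"integral"` or `"at_median"`.
#' @return named numeric vector (`ed`, `nonelective_days`,
#'   `elective_days`) with attribute `"method"`.
#' @export
lifetime_resource_use <- function(model, profile, method = NULL) {
  profile <- check_profile(model, profile)
  method <- match.arg(method %||% model$lifetime_count_method,
    c("integral", "at_median"))
  H <- model$truncation_age - profile$age[1]
  out <- numeric(3)
  names(out) <- c("ed", "nonelective_days", "elective_days")
  keys <- c(ed = "ed", nonelective_days = "nonelective", elective_days = "elective")
  if (method == "integral") {
    S <- survival_function(model, profile)
    for (nm in names(keys)) {
      lam <- resource_intensity(model, keys[[nm]], profile)
      out[nm] <- surv_weighted_integral(S, lam, H)
    }
  } else {
    med <- min(median_le(model, profile)$median, H)
    for (nm in names(keys)) {
      out[nm] <- resource_cumintensity(model, keys[[nm]], profile)(med)
    }
  }
  attr(out, "method") <- method
  out
}

#' Discounted lifetime costs and QALYs
#'
#' Costs accumulate the three resource intensities priced at the unit
#' costs, weighted by survival and discounted continuously at the annual
#' rate `r`: `cost = integral S(t) * sum_r lambda_r(t) c_r * (1+r)^(-t) dt`.
#' QALYs weight survival by the state utility:
#' `QALY = integral S(t) * u(state) * (1+r)^(-t) dt`. Undiscounted values
#' are reported alongside.
#'
#' @inheritParams survival_function
#' @param discount_rate override of the model's annual discount rate.
#' @return list with `cost`, `qalys`, `cost_undiscounted`,
#'   `qalys_undiscounted`, `life_expectancy` (undiscounted area under the
#'   survival curve), `unit_costs`, `utility`, `discount_rate`, `currency`.
#' @export
economics <- function(model, profile, discount_rate = NULL) {
  profile <- check_profile(model, profile)
  ec <- model$economics
  if (is.null(ec$utilities)) stop("model carries no utility weights")
  r <- discount_rate %||% ec$discount_rate
  u <- ec$utilities[[as.character(profile$state[1])]]
  if (is.null(u)) stop("no utility for state ", profile$state[1])
  H <- model$truncation_age - profile$age[1]
  S <- survival_function(model, profile)
  disc <- function(t) (1 + r)^(-t)
  lam <- lapply(c("ed", "nonelective", "elective"), function(k) {
    resource_intensity(model, k, profile)
  })
  costs <- unname(ec$unit_costs[c("ed_attendance", "nonelective_bed_day",
    "elective_bed_day")])
  priced <- function(t) {
    lam[[1]](t) * costs[1] + lam[[2]](t) * costs[2] + lam[[3]](t) * costs[3]
  }
  list(
    cost = surv_weighted_integral(S, function(t) priced(t) * disc(t), H),
    qalys = u * surv_weighted_integral(S, disc, H),
    cost_undiscounted = surv_weighted_integral(S, priced, H),
    qalys_undiscounted = u * surv_weighted_integral(S, function(t) rep(1, length(t)), H),
    life_expectancy = surv_weighted_integral(S, function(t) rep(1, length(t)), H),
    unit_costs = ec$unit_costs, utility = u, discount_rate = r,
    currency = ec$currency
  )
}

#' Per-profile predictions
#'
#' One row per profile: median life expectancy with interquartile range,
#' expected lifetime resource counts, discounted lifetime cost and QALYs.
#'
#' @param object a `"stroke_lifetime"` object.
#' @param newdata data frame of profiles (`age`, `sex`, `mrs` or `state`).
#' @param economics compute discounted cost/QALY columns (default TRUE).
#' @param ... unused.
#' @export
predict.stroke_lifetime <- function(object, newdata, economics = TRUE, ...) {
  newdata <- check_profile(object, newdata)
  rows <- lapply(seq_len(nrow(newdata)), function(i) {
    pr <- newdata[i, , drop = FALSE]
    le <- median_le(object, pr)
    res <- lifetime_resource_use(object, pr)
    out <- data.frame(
      age = pr$age, sex = pr$sex, state = pr$state,
      year1_death = year1_death_prob(object, pr),
      median_le = le$median, le_q25 = le$q25, le_q75 = le$q75,
      le_capped = unname(le$capped[["median"]]),
      ed = res[["ed"]], nonelective_days = res[["nonelective_days"]],
      elective_days = res[["elective_days"]]
    )
    if (economics) {
      econ <- strokelifetime::economics(object, pr)
      out$cost <- econ$cost
      out$qalys <- econ$qalys
      out$life_expectancy <- econ$life_expectancy
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two covariate profiles
#'
#' Field-wise differences (profile A minus profile B) of the per-profile
#' predictions, e.g. the life years gained by being discharged with a
#' lower mRS.
#'
#' @inheritParams survival_function
#' @param profile_a,profile_b single-row profile data frames.
#' @param ... passed to [predict.stroke_lifetime()].
#' @return list with `a`, `b` (prediction rows) and `delta` (numeric
#'   differences).
#' @export
compare_profiles <- function(model, profile_a, profile_b, ...) {
  pa <- predict(model, profile_a, ...)
  pb <- predict(model, profile_b, ...)
  num <- vapply(pa, is.numeric, logical(1))
  delta <- unlist(pa[1, num]) - unlist(pb[1, num])
  list(a = pa, b = pb, delta = delta)
}

#' Collapse the six-state model to dichotomized states
#'
#' Builds an independent (mRS 0–2) versus dependent (mRS 3–5) variant of a
#' six-state model by averaging the state coefficients of every equation
#' within each group, weighted by the discharge-state mix (default: the
#' derivation cohort's mRS distribution). The result is a synthetic
#' approximation for users whose economic models use binary dependency
#' outcomes; fitting [stroke_lifetime()] to a cohort with
#' `dichotomize = TRUE` estimates the binary equations directly instead.
#'
#' @param model a six-state `"stroke_lifetime"` object.
#' @param weights positive weights for mRS 0–5.
#' @return a `"stroke_lifetime"` object with states
#'   `independent`/`dependent`.
#' @export
dichotomize_model <- function(model, weights = c(139, 333, 366, 359, 268, 44)) {
  stopifnot(inherits(model, "stroke_lifetime"))
  if (!identical(model$states, MRS_STATES)) stop("model is already dichotomized")
  w <- weights / sum(weights)
  collapse_eq <- function(eq) {
    co <- eq$coefficients
    lev <- function(s, pre = "") {
      if (s == "0") 0 else cf(co, paste0(pre, "mrs", s))
    }
    ind <- sum(w[1:3] * vapply(MRS_STATES[1:3], lev, 0)) / sum(w[1:3])
    dep <- sum(w[4:6] * vapply(MRS_STATES[4:6], lev, 0)) / sum(w[4:6])
    ind_x <- sum(w[1:3] * vapply(MRS_STATES[1:3], lev, 0, pre = "age_x_")) / sum(w[1:3])
    dep_x <- sum(w[4:6] * vapply(MRS_STATES[4:6], lev, 0, pre = "age_x_")) / sum(w[4:6])
    keep <- setdiff(names(co), c(paste0("mrs", 1:5), paste0("age_x_mrs", 1:5)))
    out <- co[keep]
    out["intercept"] <- cf(co, "intercept") + ind
    out["dependent"] <- dep - ind
    if ("age" %in% names(out)) out["age"] <- cf(co, "age") + ind_x
    if (abs(dep_x - ind_x) > 0) out["age_x_dependent"] <- dep_x - ind_x
    eq$coefficients <- out
    eq
  }
  ec <- model$economics
  if (!is.null(ec$utilities)) {
    ec$utilities <- c(
      independent = sum(w[1:3] * ec$utilities[MRS_STATES[1:3]]) / sum(w[1:3]),
      dependent = sum(w[4:6] * ec$utilities[MRS_STATES[4:6]]) / sum(w[4:6])
    )
  }
  new_stroke_lifetime(
    mortality = list(
      year1 = collapse_eq(model$mortality$year1),
      lifetime = collapse_eq(model$mortality$lifetime),
      stage1_hr = NULL, sim_meta = model$mortality$sim_meta
    ),
    resources = lapply(model$resources[c("ed", "nonelective", "elective")], collapse_eq),
    economics = ec, states = DICHOT_STATES,
    centering_mean = model$centering_mean,
    truncation_age = model$truncation_age,
    lifetime_count_method = model$lifetime_count_method,
    metadata = c(model$metadata, list(derived = "weighted collapse of six-state model"))
  )
}

#' Plot composed survival curves
#'
#' Survival after discharge for each discharge state at a given age and
#' sex (the style of the model's published survival figure).
#'
#' @param x a `"stroke_lifetime"` object.
#' @param age,sex profile held fixed across states.
#' @param horizon plotted time range in years.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.stroke_lifetime <- function(x, age = x$centering_mean, sex = "female",
                                 horizon = 15, ...) {
  grid <- seq(0, min(horizon, x$truncation_age - age), by = 0.05)
  states <- x$states
  dich <- identical(states, DICHOT_STATES)
  S <- sapply(states, function(s) {
    pr <- if (dich) {
      data.frame(age = age, sex = sex, state = s)
    } else {
      data.frame(age = age, sex = sex, mrs = as.integer(s))
    }
    survival_function(x, pr)(grid)
  })
  graphics::matplot(grid, S,
    type = "l", lty = 1, lwd = 2, col = seq_along(states),
    xlab = "Years since discharge", ylab = "Probability of survival",
    main = sprintf("Survival by discharge state (%s, age %.1f)", sex, age),
    ylim = c(0, 1), ...
  )
  graphics::legend("topright", legend = states, col = seq_along(states),
    lty = 1, lwd = 2, bty = "n",
    title = if (identical(states, MRS_STATES)) "mRS" else "state")
  invisible(x)
}
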