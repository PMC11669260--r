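#' Year-1 mortality: logistic regression
#'
#' Fits the logistic equation for death within 12 months of discharge on
#' centered age, sex and discharge-state indicators (no interactions).
#' Patients censored alive before day 365.25 are excluded from the risk
#' set — the derivation design guarantees at least 5.7 years of follow-up,
#' so none are expected; an informative count is attached when any are.
#' Complete separation (a state cell with no deaths or no survivors) is an
#' error naming the cell; constant covariate columns (e.g. a single-sex
#' cohort) are dropped with a warning.
#'
#' @param cohort a `"stroke_cohort"`.
#' @param centering_mean age-centering constant (years).
#' @param dichotomize use the binary independent/dependent state instead
#'   of the six mRS indicators.
#' @return list with `coefficients` (bundle naming: `intercept`, `age`,
#'   `male`, `mrs1`..`mrs5` or `dependent`), `se`, `n`, `n_deaths` and the
#'   underlying `glm` fit.
#' @export
fit_year1 <- function(cohort, centering_mean = 73.69, dichotomize = FALSE) {
  stopifnot(inherits(cohort, "stroke_cohort"))
  fu_years <- cohort$followup_days / DAYS_PER_YEAR
  at_risk <- cohort$died == 1 | fu_years > 1
  n_drop <- sum(!at_risk)
  dd <- cohort[at_risk, , drop = FALSE]
  y <- as.numeric(dd$died == 1 & fu_years[at_risk] <= 1)
  if (!any(y == 1) || !any(y == 0)) {
    stop("year-1 risk set needs both deaths and survivors")
  }
  X <- state_design(dd$age, dd$sex, dd$mrs, centering_mean, dichotomize)
  ## separation check per state cell
  state <- if (dichotomize) ifelse(dd$mrs <= 2, "independent", "dependent") else dd$mrs
  tab <- table(state, y)
  bad <- rownames(tab)[tab[, "1"] == 0 | tab[, "0"] == 0]
  if (length(bad)) {
    stop("complete separation: state cell(s) ", toString(bad),
      " have no year-1 deaths or no survivors")
  }
  keep <- vapply(as.data.frame(X), function(v) stats::var(v) > 0, logical(1))
  if (any(!keep)) {
    warning("dropping constant covariate(s): ", toString(names(keep)[!keep]))
    X <- X[, keep, drop = FALSE]
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", colnames(X)), response = "y")
  g <- stats::glm(fml, family = stats::binomial(), data = df)
  co <- stats::coef(g)
  names(co)[1] <- "intercept"
  names(co) <- gsub("`", "", names(co))
  se <- sqrt(diag(stats::vcov(g)))
  names(se) <- names(co)
  list(coefficients = co, se = se, n = nrow(dd), n_deaths = sum(y),
    n_excluded_censored = n_drop, glm = g)
}

## Design matrix (no intercept column) for the state covariates used by
## the year-1 and stage-2 equations.
state_design <- function(age, sex, mrs, centering_mean, dichotomize,
                         quadratic = FALSE, interactions = FALSE) {
  ac <- age - centering_mean
  male <- as.numeric(check_sex(sex) == "male")
  X <- cbind(age = ac, male = male)
  if (quadratic) X <- cbind(X[, "age", drop = FALSE], age_sq = ac^2,
    male = male)
  if (dichotomize) {
    dep <- as.numeric(mrs >= 3)
    X <- cbind(X, dependent = dep)
    if (interactions) X <- cbind(X, age_x_dependent = ac * dep)
  } else {
    for (k in 1:5) {
      X <- cbind(X, as.numeric(mrs == k))
      colnames(X)[ncol(X)] <- paste0("mrs", k)
    }
    if (interactions) {
      for (k in 1:5) {
        X <- cbind(X, ac * as.numeric(mrs == k))
        colnames(X)[ncol(X)] <- paste0("age_x_mrs", k)
      }
    }
  }
  X
}

## Shared machinery: fit a Gompertz to a fixed design with replicate-varying
## stop times, averaging coefficients across converged replicates.
replicate_gompertz <- function(X, start, stop_fun, event, n_sims, seed,
                               label) {
  fits <- vector("list", n_sims)
  dropped <- 0L
  warm <- NULL
  dat <- data.frame(start = start, event = event)
  for (r in seq_len(n_sims)) {
    set.seed(seed + r)
    dat$stop <- stop_fun()
    dat2 <- cbind(dat, as.data.frame(X))
    f <- try(surv_mle(dat2, "gompertz",
      formula = stats::reformulate(sprintf("`%s`", colnames(X))),
      init = warm), silent = TRUE)
    if (inherits(f, "try-error") || !isTRUE(f$converged)) {
      dropped <- dropped + 1L
      next
    }
    warm <- f$theta
    fits[[r]] <- f
  }
  fits <- Filter(Negate(is.null), fits)
  if (dropped > 0.2 * n_sims) {
    stop(label, ": ", dropped, " of ", n_sims,
      " replicates failed to converge (> 20%)")
  }
  cm <- Reduce(`+`, lapply(fits, function(f) c(f$coefficients, gamma = f$shape))) /
    length(fits)
  sem <- Reduce(`+`, lapply(fits, function(f) f$se)) / length(fits)
  names(cm)[1] <- "intercept"
  names(cm) <- gsub("`", "", names(cm))
  names(sem) <- c(names(cm)[-length(cm)], "gamma")
  list(coefficients = cm[-length(cm)], gamma = unname(cm["gamma"]),
    se = sem, n_reps = length(fits), n_dropped = dropped)
}

#' Stage 1: excess mortality versus synthetic population controls
#'
#' For each replicate, one synthetic control per stroke patient is created
#' with the same age and sex; the control's death time is sampled from the
#' life table (hazard ratio 1). The combined stroke + control data are
#' fitted by a Gompertz model on time since discharge with centered age,
#' sex and per-state indicators (controls as reference). Coefficients are
#' averaged across converged replicates; the per-state hazard ratios of
#' death versus the general population are the exponentials of the
#' averaged state coefficients.
#'
#' @param cohort a `"stroke_cohort"`.
#' @param lt a `"life_table"`.
#' @param n_sims number of simulation replicates.
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @inheritParams fit_year1
#' @return list with `hr` (named hazard ratios per state),
#'   `coefficients`, `gamma`, `se`, `n_reps`, `n_dropped`.
#' @export
stage1 <- function(cohort, lt, n_sims = 200, seed = 1, centering_mean = 73.69,
                   dichotomize = FALSE) {
  stopifnot(inherits(cohort, "stroke_cohort"), inherits(lt, "life_table"))
  n <- nrow(cohort)
  fu <- pmax(cohort$followup_days / DAYS_PER_YEAR, 0.5 / DAYS_PER_YEAR)
  ## state design: per-state indicators for stroke rows, all zero for controls
  ac <- cohort$age - centering_mean
  male <- as.numeric(cohort$sex == "male")
  states <- if (dichotomize) DICHOT_STATES else MRS_STATES
  state_of <- if (dichotomize) {
    ifelse(cohort$mrs <= 2, "independent", "dependent")
  } else {
    as.character(cohort$mrs)
  }
  Xs <- cbind(age = ac, male = male)
  lab <- function(s) if (dichotomize) s else paste0("mrs", s)
  for (s in states) {
    Xs <- cbind(Xs, as.numeric(state_of == s))
    colnames(Xs)[ncol(Xs)] <- lab(s)
  }
  X <- rbind(Xs, cbind(age = ac, male = male,
    matrix(0, n, length(states), dimnames = list(NULL, vapply(states, lab, "")))))
  start <- rep(0, 2 * n)
  event <- c(as.numeric(cohort$died == 1), rep(1, n))
  age0 <- pmin(cohort$age, 100)
  stop_fun <- function() {
    da <- sample_death_age(lt, age0, cohort$sex, hr = 1)
    c(fu, pmax(da - age0, 0.5 / DAYS_PER_YEAR))
  }
  out <- replicate_gompertz(X, start, stop_fun, event, n_sims, seed, "stage 1")
  hr <- exp(out$coefficients[vapply(states, lab, "")])
  names(hr) <- states
  c(list(hr = hr), out)
}

#' Stage 2: the lifetime Gompertz equation
#'
#' Per replicate, every patient alive at censoring is given an imputed
#' future death age sampled from the life table scaled by the stage-1
#' hazard ratio of their discharge state; lifespan is truncated at age 100
#' (forced death within [100, 101)). The completed post-year-1 dataset
#' (year-1 survivors only, delayed entry at one year, all records ending
#' in death) is fitted by a Gompertz model on centered age, age squared,
#' sex, state indicators and age-by-state interactions. Coefficients are
#' averaged across replicates.
#'
#' @inheritParams stage1
#' @param stage1_hr named per-state hazard ratios from [stage1()].
#' @return list with `coefficients` (bundle naming), `gamma`, `se`,
#'   `n_reps`, `n_dropped`, `n_imputed`.
#' @export
stage2 <- function(cohort, stage1_hr, lt, n_sims = 200, seed = 1,
                   centering_mean = 73.69, dichotomize = FALSE) {
  stopifnot(inherits(cohort, "stroke_cohort"), inherits(lt, "life_table"))
  fu <- cohort$followup_days / DAYS_PER_YEAR
  keep <- fu > 1 # alive at the end of year 1
  dd <- cohort[keep, , drop = FALSE]
  fu <- fu[keep]
  state_of <- if (dichotomize) {
    ifelse(dd$mrs <= 2, "independent", "dependent")
  } else {
    as.character(dd$mrs)
  }
  hr <- stage1_hr[state_of]
  if (any(is.na(hr))) stop("stage1_hr lacks an entry for some state")
  X <- state_design(dd$age, dd$sex, dd$mrs, centering_mean, dichotomize,
    quadratic = TRUE, interactions = TRUE)
  cens <- dd$died == 0
  cur_age <- pmin(dd$age + fu, 100)
  obs_stop <- fu
  stop_fun <- function() {
    s <- obs_stop
    if (any(cens)) {
      da <- sample_death_age(lt, cur_age[cens], dd$sex[cens], hr = hr[cens])
      s[cens] <- fu[cens] + pmax(da - cur_age[cens], 0.5 / DAYS_PER_YEAR)
    }
    s
  }
  out <- replicate_gompertz(X, rep(1, nrow(dd)), stop_fun,
    rep(1, nrow(dd)), n_sims, seed, "stage 2")
  out$n_imputed <- sum(cens)
  out
}
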