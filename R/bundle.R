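#' The lifetime stroke outcome model object
#'
#' A `"stroke_lifetime"` object bundles every fitted equation of the model:
#'
#' * `mortality$year1` — logistic equation for the log-odds of death within
#'   12 months of discharge (age centered, sex, mRS indicators);
#' * `mortality$lifetime` — Gompertz survival equation beyond year 1 (age,
#'   age squared, sex, mRS indicators, age-by-mRS interactions);
#' * `mortality$stage1_hr` — hazard ratios of death per discharge state
#'   versus matched general-population controls (first simulation stage);
#' * `resources$ed`, `resources$nonelective`, `resources$elective` —
#'   recurrent-event intensity equations (Weibull for ED attendances,
#'   log-logistic for non-elective and elective bed days);
#' * `economics` — unit costs per resource, utility weight per state,
#'   annual discount rate;
#' * `states` — either the six mRS levels `"0"`–`"5"` or the dichotomized
#'   pair `"independent"`/`"dependent"`.
#'
#' Objects are produced by the fitting function [stroke_lifetime()], by
#' [read_bundle()] from a JSON coefficient bundle, or by
#' [calibrate_reference_bundle()] from published prediction grids.
#'
#' @name stroke_lifetime-class
NULL

MRS_STATES <- as.character(0:5)
DICHOT_STATES <- c("independent", "dependent")

new_stroke_lifetime <- function(mortality, resources, economics = default_economics(),
                                states = MRS_STATES, centering_mean = 73.69,
                                truncation_age = 100,
                                lifetime_count_method = "integral",
                                fits = NULL, metadata = list()) {
  obj <- structure(list(
    mortality = mortality, resources = resources, economics = economics,
    states = states, centering_mean = centering_mean,
    truncation_age = truncation_age,
    lifetime_count_method = match.arg(lifetime_count_method, c("integral", "at_median")),
    fits = fits, metadata = metadata
  ), class = "stroke_lifetime")
  validate_stroke_lifetime(obj)
  obj
}

validate_stroke_lifetime <- function(x) {
  stopifnot(inherits(x, "stroke_lifetime"))
  if (!identical(x$states, MRS_STATES) && !identical(x$states, DICHOT_STATES)) {
    stop("states must be mRS 0-5 or independent/dependent")
  }
  if (is.null(x$mortality$year1$coefficients) ||
    is.null(x$mortality$lifetime$coefficients)) {
    stop("model must carry year-1 logistic and lifetime coefficients")
  }
  if (!identical(x$mortality$lifetime$family, "gompertz")) {
    stop("the lifetime mortality equation must be Gompertz")
  }
  for (r in c("ed", "nonelective", "elective")) {
    eq <- x$resources[[r]]
    if (is.null(eq)) stop("missing resource equation: ", r)
    check_family(eq$family)
    if (family_has_shape(eq$family) && is.null(eq$shape)) {
      stop("resource equation '", r, "' lacks its ancillary parameter")
    }
  }
  ec <- x$economics
  if (!is.null(ec)) {
    if (any(ec$unit_costs < 0)) stop("unit costs must be >= 0")
    if (!is.null(ec$utilities) && any(abs(ec$utilities) > 1)) {
      stop("utilities must lie in [-1, 1]")
    }
    if (ec$discount_rate < 0 || ec$discount_rate >= 1) {
      stop("discount rate must lie in [0, 1)")
    }
  }
  invisible(x)
}

#' Default economic parameters
#'
#' Unit costs are the published secondary-care costs the model was released
#' with: £137 per ED attendance, £533 per non-elective bed day, £444 per
#' elective bed day. The per-state utility weights are an *illustrative,
#' synthetic* set taken from the utility-weighted mRS literature (0.97,
#' 0.88, 0.74, 0.55, 0.20, -0.19 for mRS 0-5); substitute study-specific
#' utilities for any real economic evaluation. Discounting defaults to the
#' UK reference-case 3.5% per year.
#'
#' @param states state labels (mRS levels or dichotomized pair).
#' @export
default_economics <- function(states = MRS_STATES) {
  u <- if (identical(states, DICHOT_STATES)) {
    c(independent = 0.86, dependent = 0.19)
  } else {
    stats::setNames(c(0.97, 0.88, 0.74, 0.55, 0.20, -0.19), MRS_STATES)
  }
  list(
    unit_costs = c(ed_attendance = 137, nonelective_bed_day = 533,
      elective_bed_day = 444),
    utilities = u,
    discount_rate = 0.035,
    currency = "GBP"
  )
}

## Coefficient lookup: absent terms contribute 0.
cf <- function(coefs, name) if (name %in% names(coefs)) unname(coefs[name]) else 0

## Evaluate a bundle equation's linear predictor for a profile data frame.
eval_lp <- function(eq, profile, centering_mean, states) {
  co <- eq$coefficients
  ac <- profile$age - centering_mean
  lp <- cf(co, "intercept") + cf(co, "age") * ac + cf(co, "age_sq") * ac^2 +
    cf(co, "male") * as.numeric(profile$sex == "male")
  st <- as.character(profile$state)
  for (s in states[-1]) {
    term <- if (identical(states, DICHOT_STATES)) s else paste0("mrs", s)
    ind <- as.numeric(st == s)
    lp <- lp + cf(co, term) * ind + cf(co, paste0("age_x_", term)) * ac * ind
  }
  lp
}

## Normalize a profile data frame against a model's state set.
check_profile <- function(model, profile) {
  profile <- as.data.frame(profile)
  need <- c("age", "sex")
  if (!all(need %in% names(profile))) {
    stop("profile needs columns age and sex plus mrs (or state)")
  }
  profile$sex <- check_sex(profile$sex)
  if (any(profile$age < 0 | profile$age > 100)) {
    stop("profile age must lie within the life-table support [0, 100]")
  }
  dich <- identical(model$states, DICHOT_STATES)
  if (!is.null(profile$state)) {
    ## already normalized profiles pass straight through; a state label
    ## from the other mode is a mixing error
    if (!all(profile$state %in% model$states)) {
      if (!dich && all(profile$state %in% DICHOT_STATES)) {
        stop("this model uses the six mRS states; supply 'mrs', not 'state'")
      }
      stop("profile state must be one of: ", toString(model$states))
    }
  } else {
    if (is.null(profile$mrs)) stop("profile needs 'mrs' (or 'state')")
    if (any(!(profile$mrs %in% 0:5))) stop("mrs must be an integer in 0-5")
    profile$state <- if (dich) {
      ifelse(profile$mrs <= 2, "independent", "dependent")
    } else {
      as.character(profile$mrs)
    }
  }
  if (any(!(profile$state %in% model$states))) {
    stop("profile state must be one of: ", toString(model$states))
  }
  profile
}

#' Year-1 death probability for covariate profiles
#'
#' Inverse-logit of the year-1 logistic equation.
#'
#' @param model a `"stroke_lifetime"` object.
#' @param profile data frame with `age`, `sex` and `mrs` (or `state`).
#' @export
year1_death_prob <- function(model, profile) {
  profile <- check_profile(model, profile)
  stats::plogis(eval_lp(model$mortality$year1, profile, model$centering_mean, model$states))
}

#' Read and write coefficient bundles (JSON)
#'
#' The JSON bundle is the interchange format between estimation and
#' prediction. Each equation is stored as
#' `{family, coefficients: {...}, shape: {<label>: value}}` where the
#' ancillary-parameter label must match the family convention: `ln_p`
#' (Weibull, logged), `gamma` (Gompertz, natural scale), `ln_gamma`
#' (log-logistic, logged), `ln_scale` (logistic, logged). Logged
#' ancillaries are exponentiated on load; a label/family mismatch or an
#' unknown field is an error.
#'
#' @param path JSON file path.
#' @return `read_bundle()`: a `"stroke_lifetime"` object.
#' @export
read_bundle <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("schema_version", "model_type", "centering_mean", "truncation_age",
    "mortality", "resources", "economics", "lifetime_count_method", "metadata")
  unknown <- setdiff(names(js), known)
  if (length(unknown)) stop("bundle has unknown field(s): ", toString(unknown))
  states <- switch(js$model_type %||% "mrs6",
    mrs6 = MRS_STATES, dichotomized = DICHOT_STATES,
    stop("unknown model_type: ", js$model_type)
  )
  load_eq <- function(e, name) {
    fam <- check_family(e$family)
    out <- list(family = fam, coefficients = unlist(e$coefficients))
    if (family_has_shape(fam)) {
      lab <- family_shape_label(fam)
      if (is.null(e$shape) || !identical(names(e$shape), lab)) {
        stop("equation '", name, "' (", fam, "): ancillary parameter must be ",
          "labelled '", lab, "', got '", toString(names(e$shape)), "'")
      }
      val <- e$shape[[lab]]
      out$shape <- if (family_shape_logged(fam)) exp(val) else val
    } else if (!is.null(e$shape)) {
      stop("equation '", name, "': exponential family takes no ancillary parameter")
    }
    out
  }
  y1 <- list(coefficients = unlist(js$mortality$year1$coefficients))
  mort <- list(
    year1 = y1,
    lifetime = load_eq(js$mortality$lifetime, "lifetime"),
    stage1_hr = if (!is.null(js$mortality$stage1_hr)) unlist(js$mortality$stage1_hr),
    sim_meta = js$mortality$sim_meta
  )
  res <- list(
    ed = load_eq(js$resources$ed, "ed"),
    nonelective = load_eq(js$resources$nonelective, "nonelective"),
    elective = load_eq(js$resources$elective, "elective")
  )
  ec <- js$economics
  if (!is.null(ec)) {
    ec$unit_costs <- unlist(ec$unit_costs)
    ec$utilities <- unlist(ec$utilities)
  } else {
    ec <- default_economics(states)
  }
  new_stroke_lifetime(
    mortality = mort, resources = res, economics = ec, states = states,
    centering_mean = js$centering_mean %||% 73.69,
    truncation_age = js$truncation_age %||% 100,
    lifetime_count_method = js$lifetime_count_method %||% "integral",
    metadata = js$metadata %||% list()
  )
}

#' @rdname read_bundle
#' @param model a `"stroke_lifetime"` object.
#' @export
write_bundle <- function(model, path) {
  validate_stroke_lifetime(model)
  dump_eq <- function(e) {
    out <- list(family = e$family, coefficients = as.list(e$coefficients))
    if (family_has_shape(e$family)) {
      lab <- family_shape_label(e$family)
      val <- if (family_shape_logged(e$family)) log(e$shape) else e$shape
      out$shape <- stats::setNames(list(val), lab)
    }
    out
  }
  js <- list(
    schema_version = "1.0",
    model_type = if (identical(model$states, DICHOT_STATES)) "dichotomized" else "mrs6",
    centering_mean = model$centering_mean,
    truncation_age = model$truncation_age,
    mortality = list(
      year1 = list(
        family = "logistic-binary",
        coefficients = as.list(model$mortality$year1$coefficients)
      ),
      lifetime = dump_eq(model$mortality$lifetime),
      stage1_hr = if (!is.null(model$mortality$stage1_hr)) {
        as.list(model$mortality$stage1_hr)
      },
      sim_meta = model$mortality$sim_meta
    ),
    resources = lapply(model$resources[c("ed", "nonelective", "elective")], dump_eq),
    economics = list(
      unit_costs = as.list(model$economics$unit_costs),
      utilities = as.list(model$economics$utilities),
      discount_rate = model$economics$discount_rate,
      currency = model$economics$currency
    ),
    lifetime_count_method = model$lifetime_count_method,
    metadata = model$metadata
  )
  js$mortality <- js$mortality[!vapply(js$mortality, is.null, logical(1))]
  js <- js[!vapply(js, is.null, logical(1))]
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The packaged reference coefficient bundle
#'
#' Returns the model calibrated to the published prediction grids (see
#' [calibrate_reference_bundle()] and `data-raw/make_reference_bundle.R`).
#' This is a synthetic stand-in for the original fitted coefficient tables,
#' which are not redistributed here: the coefficients were chosen by least
#' squares so that the model reproduces the published survival-probability
#' and lifetime-prediction grids.
#'
#' @return a `"stroke_lifetime"` object.
#' @export
reference_model <- function() {
  read_bundle(system.file("extdata", "reference_bundle_synthetic.json",
    package = "strokelifetime", mustWork = TRUE))
}

#' @export
print.stroke_lifetime <- function(x, ...) {
  dich <- identical(x$states, DICHOT_STATES)
  cat("Lifetime stroke outcome model (",
    if (dich) "dichotomized states" else "mRS 0-5", ")\n", sep = "")
  cat("  year-1 mortality: logistic;  lifetime: Gompertz (gamma =",
    format(x$mortality$lifetime$shape, digits = 4), ")\n")
  cat("  resources: ED =", x$resources$ed$family,
    "| non-elective =", x$resources$nonelective$family,
    "| elective =", x$resources$elective$family, "\n")
  if (!is.null(x$mortality$stage1_hr)) {
    cat("  stage-1 hazard ratios vs population:",
      paste(sprintf("%s=%.2f", names(x$mortality$stage1_hr),
        x$mortality$stage1_hr), collapse = " "), "\n")
  }
  cat("  age centering:", x$centering_mean, "years; horizon: age",
    x$truncation_age, "\n")
  invisible(x)
}

#' @export
coef.stroke_lifetime <- function(object, ...) {
  list(
    year1 = object$mortality$year1$coefficients,
    lifetime = c(object$mortality$lifetime$coefficients,
      gamma = object$mortality$lifetime$shape),
    ed = c(object$resources$ed$coefficients, shape = object$resources$ed$shape),
    nonelective = c(object$resources$nonelective$coefficients,
      shape = object$resources$nonelective$shape),
    elective = c(object$resources$elective$coefficients,
      shape = object$resources$elective$shape)
  )
}

#' @export
summary.stroke_lifetime <- function(object, ...) {
  print(object)
  cat("\nCoefficients:\n")
  cfs <- coef(object)
  for (nm in names(cfs)) {
    cat(" ", nm, ":\n")
    print(round(cfs[[nm]], 5))
  }
  invisible(cfs)
}
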