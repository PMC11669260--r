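#' Parametric time-to-event families
#'
#' The model uses five parametric families for time-to-event processes:
#' exponential, Weibull, logistic, log-logistic and Gompertz. Conventions
#' follow the proportional-hazards metric for exponential, Weibull and
#' Gompertz (covariates act multiplicatively on the hazard through
#' `exp(lp)`) and the accelerated-failure-time metric for the log-logistic
#' (covariates act on the scale through `exp(lp)`) and logistic families,
#' matching the conventions under which the reference coefficient sets were
#' produced:
#'
#' * exponential: `h(t) = exp(lp)`
#' * Weibull:     `h(t) = p * t^(p-1) * exp(lp)`, shape `p > 0`
#' * Gompertz:    `h(t) = exp(lp) * exp(gamma * t)`, `gamma` unrestricted
#' * log-logistic: `S(t) = 1 / (1 + (t/exp(lp))^(1/gamma))`, `gamma > 0`
#' * logistic:    logistic distribution on time with location `lp` and
#'   scale `gamma > 0`, left-truncated at zero so that `S(0) = 1`
#'
#' `lp` is the linear predictor. Time is measured in years since discharge.
#'
#' @name surv-families
#' @keywords internal
NULL

## Admissible family names, in the fixed enumeration order used for
## deterministic AIC tie-breaking.
surv_families <- function() {
  c("exponential", "weibull", "logistic", "loglogistic", "gompertz")
}

check_family <- function(family) {
  family <- match.arg(family, surv_families())
  family
}

family_has_shape <- function(family) {
  check_family(family) != "exponential"
}

## TRUE when the ancillary parameter is optimized / stored on the log scale
## (Weibull p, log-logistic gamma, logistic scale); the Gompertz gamma is
## unrestricted in sign and kept on the natural scale.
family_shape_logged <- function(family) {
  check_family(family) %in% c("weibull", "loglogistic", "logistic")
}

## JSON label the bundle format uses for the ancillary parameter.
family_shape_label <- function(family) {
  switch(check_family(family),
    exponential = NA_character_,
    weibull     = "ln_p",
    gompertz    = "gamma",
    loglogistic = "ln_gamma",
    logistic    = "ln_scale"
  )
}

## Gompertz integrated-hazard kernel g(t) = (exp(gamma t) - 1) / gamma and
## its gamma-derivative, stable as gamma -> 0.
gompertz_g <- function(t, gamma) {
  if (abs(gamma) < 1e-10) t * (1 + gamma * t / 2) else expm1(gamma * t) / gamma
}
gompertz_dg <- function(t, gamma) {
  if (abs(gamma) < 1e-10) {
    t^2 / 2 + gamma * t^3 / 3
  } else {
    (t * exp(gamma * t) - gompertz_g(t, gamma)) / gamma
  }
}

## Hazard h(t | lp, shape); vectorized over t and lp.
family_hazard <- function(family, t, lp, shape = NULL) {
  switch(check_family(family),
    exponential = exp(lp) + 0 * t,
    weibull     = shape * t^(shape - 1) * exp(lp),
    gompertz    = exp(lp + shape * t),
    loglogistic = {
      a <- 1 / shape
      z <- exp(a * (log(t) - lp))
      a * z / (t * (1 + z))
    },
    logistic    = {
      u <- (t - lp) / shape
      stats::dlogis(u) / shape / (1 - stats::plogis(u))
    }
  )
}

## Cumulative hazard H(t | lp, shape) from time 0.
family_cumhaz <- function(family, t, lp, shape = NULL) {
  switch(check_family(family),
    exponential = exp(lp) * t,
    weibull     = exp(lp) * t^shape,
    gompertz    = exp(lp) * gompertz_g(t, shape),
    loglogistic = {
      z <- ifelse(t > 0, exp((log(t) - lp) / shape), 0)
      log1p(z)
    },
    logistic    = {
      ## S(t) = (1 - F(t)) / (1 - F(0)) for the left-truncated logistic
      s1 <- stats::plogis((t - lp) / shape, lower.tail = FALSE, log.p = TRUE)
      s0 <- stats::plogis((0 - lp) / shape, lower.tail = FALSE, log.p = TRUE)
      -(s1 - s0)
    }
  )
}

family_surv <- function(family, t, lp, shape = NULL) {
  exp(-family_cumhaz(family, t, lp, shape))
}

## Quantile: smallest t with S(t) = 1 - q, i.e. P(T <= t) = q.
family_quantile <- function(family, q, lp, shape = NULL) {
  stopifnot(all(q > 0 & q < 1))
  switch(check_family(family),
    exponential = -log1p(-q) / exp(lp),
    weibull     = (-log1p(-q) / exp(lp))^(1 / shape),
    gompertz    = {
      arg <- 1 + shape * (-log1p(-q)) * exp(-lp)
      ifelse(arg > 0, log(arg) / shape, Inf)
    },
    loglogistic = exp(lp) * (q / (1 - q))^shape,
    logistic    = {
      f0 <- stats::plogis((0 - lp) / shape)
      ft <- 1 - (1 - q) * (1 - f0)
      lp + shape * stats::qlogis(ft)
    }
  )
}

## Inverse of the cumulative hazard: t with H(t) = w (used to sample
## inhomogeneous Poisson event streams exactly).
family_cuminv <- function(family, w, lp, shape = NULL) {
  switch(check_family(family),
    exponential = w / exp(lp),
    weibull     = (w / exp(lp))^(1 / shape),
    gompertz    = {
      arg <- 1 + shape * w * exp(-lp)
      ifelse(arg > 0, log(arg) / shape, Inf)
    },
    loglogistic = exp(lp) * expm1(w)^shape,
    logistic    = {
      f0 <- stats::plogis((0 - lp) / shape)
      ft <- 1 - (1 - f0) * exp(-w)
      lp + shape * stats::qlogis(ft)
    }
  )
}

## Random draw via probability-integral transform (used by the synthetic
## cohort generator and Monte-Carlo oracles). Conditional on T > t0 when
## t0 > 0 (left truncation).
family_rand <- function(family, n, lp, shape = NULL, t0 = 0, rng_u = NULL) {
  u <- if (is.null(rng_u)) stats::runif(n) else rng_u
  if (any(t0 > 0)) {
    ## S(t) = S(t0) * u  =>  q = 1 - S(t0) * u
    s0 <- family_surv(family, t0, lp, shape)
    q <- 1 - s0 * u
  } else {
    q <- 1 - u
  }
  family_quantile(family, q, lp, shape)
}
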