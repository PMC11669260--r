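#' Censored maximum-likelihood fitting of parametric survival families
#'
#' `surv_mle()` fits one of the five parametric families (see
#' [surv-families]) to a counting-process event table by maximum
#' likelihood, honouring right censoring and delayed entry. Each row
#' contributes `h(stop)^event * S(stop) / S(start)` to the likelihood, so
#' recurrent-event tables produced by [expand_events()] (one at-risk
#' interval per event with delayed entry on the total-time scale) are fitted
#' without modification.
#'
#' Positive ancillary parameters (Weibull `p`, log-logistic `gamma`,
#' logistic scale) are optimized on the log scale; the Gompertz `gamma` is
#' unrestricted. Optimization is quasi-Newton (BFGS) with analytic
#' gradients for all families except the logistic, with up to three restarts
#' from perturbed starting values on non-convergence.
#'
#' @param data data frame with columns `start`, `stop` (years, `stop >
#'   start >= 0`), `event` (0/1) and any covariates used by `formula`.
#' @param family one of `"exponential"`, `"weibull"`, `"logistic"`,
#'   `"loglogistic"`, `"gompertz"`.
#' @param formula right-hand-side formula for the linear predictor,
#'   evaluated in `data` (default `~ 1`).
#' @param init optional starting values on the optimization scale
#'   (coefficients followed by the transformed ancillary), e.g. the
#'   solution of a previous fit to a perturbed replicate.
#' @return an object of class `"parsurv"` with elements `family`,
#'   `coefficients`, `shape` (natural scale, `NULL` for exponential),
#'   `loglik`, `aic`, `n_obs`, `n_event`, `converged`, `se`, `vcov` and
#'   `formula`.
#' @examples
#' d <- data.frame(start = 0, stop = rexp(200, 0.3), event = 1)
#' f <- surv_mle(d, "exponential")
#' exp(coef(f))  # close to 0.3
#' @export
surv_mle <- function(data, family, formula = ~1, init = NULL) {
  family <- check_family(family)
  stopifnot(all(c("start", "stop", "event") %in% names(data)))
  start <- as.numeric(data$start)
  stop_ <- as.numeric(data$stop)
  event <- as.numeric(data$event)
  if (any(start < 0) || any(stop_ <= start)) {
    stop("event table must satisfy stop > start >= 0 on every row")
  }
  if (!any(event > 0)) {
    stop("cannot fit a parametric hazard to an all-censored event table")
  }
  X <- stats::model.matrix(formula, data)
  k_lp <- ncol(X)
  has_shape <- family_has_shape(family)
  k <- k_lp + as.integer(has_shape)

  nll_gr <- parsurv_nll_gr(family, X, start, stop_, event)
  theta0 <- parsurv_start(family, X, start, stop_, event)
  if (!is.null(init)) {
    stopifnot(length(init) == k)
    theta0 <- init
  }

  fit <- NULL
  for (attempt in 0:3) {
    th <- theta0
    if (attempt > 0) { # deterministic perturbed restarts
      th <- theta0 + (attempt - 2) * 0.5 * c(rep(0.2, k_lp), rep(1, k - k_lp))
      th[1] <- theta0[1] + (attempt - 2) * 0.5
    }
    res <- try(stats::optim(th, nll_gr$fn, nll_gr$gr,
      method = "BFGS",
      control = list(maxit = 1000, reltol = 1e-14)
    ), silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$value)) next
    g <- if (is.null(nll_gr$gr)) num_grad(nll_gr$fn, res$par) else nll_gr$gr(res$par)
    ok <- res$convergence == 0 && all(is.finite(g)) &&
      max(abs(g)) < 1e-4 * max(1, abs(res$value))
    if (is.null(fit) || res$value < fit$value) {
      fit <- res
      fit$grad_ok <- ok
    }
    if (ok) break
  }
  if (is.null(fit)) stop("likelihood optimization failed for family '", family, "'")

  H <- stats::optimHess(fit$par, nll_gr$fn, nll_gr$gr)
  vcov <- try(solve(H), silent = TRUE)
  if (inherits(vcov, "try-error") || any(!is.finite(vcov)) ||
    any(diag(vcov) <= 0)) {
    vcov <- matrix(NA_real_, k, k)
  }
  theta <- fit$par
  beta <- theta[seq_len(k_lp)]
  names(beta) <- colnames(X)
  shape <- NULL
  if (has_shape) {
    shape <- theta[k]
    if (family_shape_logged(family)) shape <- exp(shape)
  }
  se <- sqrt(diag(vcov))
  names(se) <- c(colnames(X), if (has_shape) "shape")
  dimnames(vcov) <- list(names(se), names(se))
  ll <- -fit$value
  structure(list(
    family = family, coefficients = beta, shape = shape,
    loglik = ll, aic = 2 * k - 2 * ll, n_obs = length(stop_),
    n_event = sum(event), k = k, converged = isTRUE(fit$grad_ok),
    se = se, vcov = vcov, formula = formula, theta = theta
  ), class = "parsurv")
}

## Starting values: intercept from the exponential occurrence/exposure rate
## (or log median event time for AFT families); other coefficients 0.
parsurv_start <- function(family, X, start, stop_, event) {
  k_lp <- ncol(X)
  rate <- sum(event) / sum(stop_ - start)
  b0 <- numeric(k_lp)
  if (family %in% c("loglogistic", "logistic")) {
    med <- stats::median(stop_[event > 0])
    b0[1] <- if (family == "logistic") med else log(med)
  } else {
    b0[1] <- log(rate)
  }
  shape0 <- switch(family,
    exponential = NULL,
    weibull = 0,                      # log p = 0
    gompertz = 1e-3,
    loglogistic = 0,                  # log gamma = 0
    logistic = log(max(stats::median(stop_[event > 0]) / 2, 0.1))
  )
  c(b0, shape0)
}

## Negative log-likelihood and gradient closures for one design/family.
parsurv_nll_gr <- function(family, X, start, stop_, event) {
  k_lp <- ncol(X)
  d <- event
  has_start <- any(start > 0)
  logt1 <- log(stop_)
  ev <- d > 0

  if (family == "exponential") {
    fn <- function(th) {
      lp <- drop(X %*% th)
      -(sum(lp[ev]) - sum(exp(lp) * (stop_ - start)))
    }
    gr <- function(th) {
      lp <- drop(X %*% th)
      w <- d - exp(lp) * (stop_ - start)
      -drop(crossprod(X, w))
    }
  } else if (family == "weibull") {
    logt0 <- ifelse(start > 0, log(start), 0)
    fn <- function(th) {
      lp <- drop(X %*% th[seq_len(k_lp)])
      p <- exp(th[k_lp + 1])
      dH <- exp(lp) * (stop_^p - ifelse(start > 0, start^p, 0))
      -(sum(th[k_lp + 1] + (p - 1) * logt1[ev] + lp[ev]) - sum(dH))
    }
    gr <- function(th) {
      lp <- drop(X %*% th[seq_len(k_lp)])
      p <- exp(th[k_lp + 1])
      t1p <- stop_^p
      t0p <- ifelse(start > 0, start^p, 0)
      w <- d - exp(lp) * (t1p - t0p)
      gb <- -drop(crossprod(X, w))
      gs <- -(sum(d * (1 + p * logt1)) -
        p * sum(exp(lp) * (t1p * logt1 - ifelse(start > 0, t0p * logt0, 0))))
      c(gb, gs)
    }
  } else if (family == "gompertz") {
    fn <- function(th) {
      lp <- drop(X %*% th[seq_len(k_lp)])
      g <- th[k_lp + 1]
      dG <- gompertz_g(stop_, g) - if (has_start) gompertz_g(start, g) else 0
      -(sum(lp[ev] + g * stop_[ev]) - sum(exp(lp) * dG))
    }
    gr <- function(th) {
      lp <- drop(X %*% th[seq_len(k_lp)])
      g <- th[k_lp + 1]
      dG <- gompertz_g(stop_, g) - if (has_start) gompertz_g(start, g) else 0
      w <- d - exp(lp) * dG
      gb <- -drop(crossprod(X, w))
      ddG <- gompertz_dg(stop_, g) - if (has_start) gompertz_dg(start, g) else 0
      gs <- -(sum(d * stop_) - sum(exp(lp) * ddG))
      c(gb, gs)
    }
  } else if (family == "loglogistic") {
    fn <- function(th) {
      lp <- drop(X %*% th[seq_len(k_lp)])
      a <- exp(-th[k_lp + 1]) # 1/gamma
      z1 <- exp(a * (logt1 - lp))
      z0 <- ifelse(start > 0, exp(a * (log(start) - lp)), 0)
      logh <- log(a) - logt1 + a * (logt1 - lp) - log1p(z1)
      -(sum(logh[ev]) - sum(log1p(z1) - log1p(z0)))
    }
    gr <- function(th) {
      lp <- drop(X %*% th[seq_len(k_lp)])
      a <- exp(-th[k_lp + 1])
      z1 <- exp(a * (logt1 - lp))
      z0 <- ifelse(start > 0, exp(a * (log(start) - lp)), 0)
      r1 <- z1 / (1 + z1)
      r0 <- z0 / (1 + z0)
      ## d(loglik)/d lp per row
      wb <- -d * a / (1 + z1) + a * r1 - a * r0
      gb <- -drop(crossprod(X, wb))
      ## d/d log(gamma); z*log(z) -> 0 as z -> 0
      zlz1 <- ifelse(z1 > 0, z1 * log(z1), 0)
      zlz0 <- ifelse(z0 > 0, z0 * log(z0), 0)
      dlogh <- -1 - a * (logt1 - lp) + zlz1 / (1 + z1)
      gs <- -(sum(dlogh[ev]) - sum(-zlz1 / (1 + z1) + zlz0 / (1 + z0)))
      c(gb, gs)
    }
  } else { # logistic (left-truncated); numeric gradient
    fn <- function(th) {
      lp <- drop(X %*% th[seq_len(k_lp)])
      sc <- exp(th[k_lp + 1])
      H1 <- family_cumhaz("logistic", stop_, lp, sc)
      H0 <- if (has_start) family_cumhaz("logistic", start, lp, sc) else 0
      h1 <- family_hazard("logistic", stop_, lp, sc)
      val <- sum(log(h1[ev])) - sum(H1 - H0)
      if (!is.finite(val)) val <- -1e10
      -val
    }
    gr <- NULL
  }
  list(fn = fn, gr = gr)
}

num_grad <- function(fn, th, eps = 1e-6) {
  vapply(seq_along(th), function(i) {
    e <- th
    e[i] <- e[i] + eps
    e2 <- th
    e2[i] <- e2[i] - eps
    (fn(e) - fn(e2)) / (2 * eps)
  }, numeric(1))
}

#' @export
coef.parsurv <- function(object, ...) object$coefficients

#' @export
logLik.parsurv <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
print.parsurv <- function(x, ...) {
  cat("Parametric survival fit —", x$family, "family\n")
  cat(sprintf(
    "  n = %d rows, %d events; logLik = %.3f, AIC = %.3f%s\n",
    x$n_obs, x$n_event, x$loglik, x$aic,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  print(round(x$coefficients, 5))
  if (!is.null(x$shape)) cat("  shape:", format(x$shape, digits = 6), "\n")
  invisible(x)
}

fit_lp <- function(fit, newdata) {
  X <- stats::model.matrix(fit$formula, newdata)
  miss <- setdiff(colnames(X), names(fit$coefficients))
  if (length(miss)) stop("newdata produces unknown columns: ", toString(miss))
  drop(X[, names(fit$coefficients), drop = FALSE] %*% fit$coefficients)
}

check_fit_usable <- function(fit) {
  if (!inherits(fit, "parsurv")) stop("not a 'parsurv' fit")
  if (!isTRUE(fit$converged)) {
    stop("refusing to predict from an unconverged '", fit$family, "' fit; ",
      "inspect the event table or try another family")
  }
}

#' Survival, cumulative hazard and quantiles from a parametric fit
#'
#' @param fit a `"parsurv"` object from [surv_mle()].
#' @param t time(s) in years since discharge, `t >= 0`.
#' @param newdata data frame of covariate profiles (one row or `length(t)`
#'   rows); omit for an intercept-only fit.
#' @return `surv_prob()` returns `S(t | x)` in `[0, 1]`; `cum_hazard()`
#'   returns `-log S`; `surv_quantile()` returns the time at which the
#'   death probability reaches `q`, capped at `horizon` with a `"capped"`
#'   attribute when the quantile is not reached.
#' @export
surv_prob <- function(fit, t, newdata = NULL) {
  check_fit_usable(fit)
  if (any(t < 0)) stop("negative time: survival is defined on t >= 0")
  lp <- if (is.null(newdata)) fit$coefficients[1] else fit_lp(fit, newdata)
  family_surv(fit$family, t, lp, fit$shape)
}

#' @rdname surv_prob
#' @export
cum_hazard <- function(fit, t, newdata = NULL) {
  check_fit_usable(fit)
  if (any(t < 0)) stop("negative time: cumulative hazard is defined on t >= 0")
  lp <- if (is.null(newdata)) fit$coefficients[1] else fit_lp(fit, newdata)
  family_cumhaz(fit$family, t, lp, fit$shape)
}

#' @rdname surv_prob
#' @param q death probability, strictly between 0 and 1.
#' @param horizon cap in years; quantiles beyond it are truncated and
#'   flagged.
#' @export
surv_quantile <- function(fit, q, newdata = NULL, horizon = Inf) {
  check_fit_usable(fit)
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly between 0 and 1")
  lp <- if (is.null(newdata)) fit$coefficients[1] else fit_lp(fit, newdata)
  tt <- family_quantile(fit$family, q, lp, fit$shape)
  capped <- !is.finite(tt) | tt > horizon
  tt[capped] <- horizon
  attr(tt, "capped") <- capped
  tt
}

#' AIC-based selection among parametric families
#'
#' `select_family()` picks the fit with minimal AIC from a list of
#' converged fits on the same data; ties are broken by fewer parameters and
#' then by the fixed family order (exponential, Weibull, logistic,
#' log-logistic, Gompertz) for determinism. `compare_families()` fits all
#' five families to one event table and tabulates the AICs.
#'
#' @param fits list of `"parsurv"` objects fitted to identical data.
#' @return `select_family()`: the winning fit. `compare_families()`: a data
#'   frame (family, k, loglik, AIC, converged) sorted by AIC with the
#'   winning fit as attribute `"best"`.
#' @export
select_family <- function(fits) {
  if (length(fits) == 0) stop("no fits to select from")
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) stop("no converged fits to select from")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  fam <- vapply(fits, function(f) f$family, character(1))
  ord <- order(round(aic, 8), k, match(fam, surv_families()))
  fits[[ord[1]]]
}

#' @rdname select_family
#' @inheritParams surv_mle
#' @param families families to compare (default all five).
#' @export
compare_families <- function(data, formula = ~1, families = surv_families()) {
  fits <- list()
  for (fam in families) {
    f <- try(surv_mle(data, fam, formula), silent = TRUE)
    if (inherits(f, "try-error") || !isTRUE(f$converged)) {
      warning("family '", fam, "' did not converge; excluded from ranking")
      next
    }
    fits[[fam]] <- f
  }
  if (!length(fits)) stop("no family converged on this event table")
  tab <- data.frame(
    family = vapply(fits, `[[`, "", "family"),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    AIC = vapply(fits, function(f) f$aic, numeric(1)),
    row.names = NULL
  )
  tab <- tab[order(tab$AIC, tab$k, match(tab$family, surv_families())), ]
  rownames(tab) <- NULL
  attr(tab, "best") <- select_family(fits)
  class(tab) <- c("parsurv_aic", "data.frame")
  tab
}

#' @export
print.parsurv_aic <- function(x, ...) {
  cat("AIC comparison of parametric families (best first):\n")
  print.data.frame(x, digits = 6)
  invisible(x)
}
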