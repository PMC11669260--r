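# Censored maximum likelihood with delayed entry, and AIC family selection.

test_that("null exponential MLE equals events over exposure", {
  set.seed(7)
  d <- data.frame(start = 0, stop = rexp(300, 0.4), event = rbinom(300, 1, 0.7))
  d$stop <- pmax(d$stop, 1e-6)
  f <- surv_mle(d, "exponential")
  expect_equal(unname(exp(coef(f))), sum(d$event) / sum(d$stop - d$start),
    tolerance = 1e-6)
  expect_true(f$converged)
  expect_equal(f$aic, 2 * 1 - 2 * f$loglik)
})

test_that("Gompertz MLE recovers generating parameters within 3 SE", {
  d <- make_gompertz_data(2000, seed = 11, lp0 = log(0.02), beta = 0.3,
    gamma = 0.09)
  f <- surv_mle(d, "gompertz", ~x)
  est <- c(coef(f), f$shape)
  truth <- c(log(0.02), 0.3, 0.09)
  expect_true(all(abs(est - truth) <= 3 * f$se), info = paste(
    "est:", toString(round(est, 3)), "se:", toString(round(f$se, 3))
  ))
})

test_that("fits agree with an independent implementation (flexsurv)", {
  library(flexsurv)
  d <- make_gompertz_data(800, seed = 3)
  for (spec in list(
    c(mine = "gompertz", theirs = "gompertz"),
    c(mine = "weibull", theirs = "weibullPH"),
    c(mine = "loglogistic", theirs = "llogis")
  )) {
    mine <- surv_mle(d, spec[["mine"]], ~x)
    theirs <- flexsurvreg(survival::Surv(stop, event) ~ x, data = d,
      dist = spec[["theirs"]])
    expect_equal(mine$loglik, theirs$loglik, tolerance = 1e-6,
      label = spec[["mine"]])
    expect_equal(unname(coef(mine)[2]), unname(theirs$res["x", "est"]),
      tolerance = 2e-3)
  }
})

test_that("delayed entry is honoured (left-truncated fit matches flexsurv)", {
  library(flexsurv)
  set.seed(21)
  n <- 1500
  tt <- strokelifetime:::family_rand("gompertz", n, log(0.05), 0.1)
  keep <- tt > 1 # subjects observed only from t = 1
  d <- data.frame(start = 1, stop = tt[keep], event = 1)
  mine <- surv_mle(d, "gompertz")
  theirs <- flexsurvreg(survival::Surv(start, stop, event) ~ 1, data = d,
    dist = "gompertz")
  expect_equal(mine$loglik, theirs$loglik, tolerance = 1e-6)
  expect_equal(unname(mine$shape), unname(theirs$res["shape", "est"]),
    tolerance = 1e-4)
  ## ignoring the truncation gives a materially different fit
  naive <- surv_mle(data.frame(start = 0, stop = d$stop, event = 1), "gompertz")
  expect_gt(abs(naive$coefficients[1] - mine$coefficients[1]), 0.05)
})

test_that("all-censored input is refused", {
  d <- data.frame(start = 0, stop = runif(50, 1, 5), event = 0)
  expect_error(surv_mle(d, "weibull"), "all-censored")
})

test_that("invalid rows are refused", {
  expect_error(
    surv_mle(data.frame(start = 2, stop = 1, event = 1), "exponential"),
    "stop > start"
  )
})

test_that("select_family takes minimal AIC with deterministic tie-breaks", {
  mk <- function(family, aic, k) {
    structure(list(family = family, aic = aic, k = k, converged = TRUE),
      class = "parsurv")
  }
  fits <- list(mk("weibull", 100.2, 3), mk("gompertz", 98.7, 3),
    mk("loglogistic", 103.0, 3))
  expect_equal(select_family(fits)$aic, 98.7)
  ## equal AIC: the family with fewer parameters wins
  fits <- list(mk("weibull", 100, 3), mk("exponential", 100, 2))
  expect_equal(select_family(fits)$family, "exponential")
  ## equal AIC and k: fixed enumeration order decides
  fits <- list(mk("gompertz", 100, 3), mk("weibull", 100, 3))
  expect_equal(select_family(fits)$family, "weibull")
  expect_error(select_family(list()), "no fits")
})

test_that("compare_families ranks the generating family first and is deterministic", {
  d <- make_gompertz_data(1500, seed = 5, gamma = 0.25)
  tab1 <- compare_families(d, ~x)
  tab2 <- compare_families(d, ~x)
  expect_identical(tab1$family, tab2$family)
  expect_equal(tab1$family[1], "gompertz")
  expect_equal(attr(tab1, "best")$family, "gompertz")
  expect_true(all(diff(tab1$AIC) >= 0))
})

test_that("predictions from an unconverged fit are refused", {
  f <- structure(list(family = "weibull", converged = FALSE), class = "parsurv")
  expect_error(surv_prob(f, 1), "unconverged")
})

test_that("negative time is a domain error", {
  d <- data.frame(start = 0, stop = rexp(100, 1) + 1e-4, event = 1)
  f <- surv_mle(d, "exponential")
  expect_error(surv_prob(f, -1), "negative")
  expect_error(cum_hazard(f, c(1, -2)), "negative")
  expect_error(surv_quantile(f, 1.2), "between 0 and 1")
})

test_that("quantiles cap at the horizon with a flag", {
  d <- data.frame(start = 0, stop = rexp(200, 0.01) + 1e-4, event = 1)
  f <- surv_mle(d, "exponential")
  q <- surv_quantile(f, 0.9, horizon = 5)
  expect_equal(unname(q[1]), 5)
  expect_true(attr(q, "capped")[1])
})

test_that("AIC ordering is invariant to covariate re-centering", {
  d <- make_gompertz_data(1200, seed = 9)
  d$x2 <- d$x - 0.5
  fam_order <- function(dd, fml) compare_families(dd, fml)$family
  expect_identical(fam_order(d, ~x), fam_order(d, ~x2))
})
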