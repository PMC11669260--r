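# Closed-form properties of the parametric families, checked against
# independent numerical oracles (quadrature of the hazard, brute-force
# CDF inversion).

fam_cases <- list(
  list(family = "exponential", lp = log(0.3), shape = NULL),
  list(family = "weibull", lp = log(0.2), shape = 1.4),
  list(family = "gompertz", lp = log(0.05), shape = 0.1),
  list(family = "gompertz", lp = log(0.05), shape = -0.05),
  list(family = "loglogistic", lp = log(5), shape = 0.5),
  list(family = "logistic", lp = 6, shape = 2)
)

test_that("survival equals exp(-integral of hazard) for every family", {
  for (cs in fam_cases) {
    for (t in c(0.5, 2, 7)) {
      H_num <- stats::integrate(function(u) {
        strokelifetime:::family_hazard(cs$family, u, cs$lp, cs$shape)
      }, 0, t, rel.tol = 1e-10)$value
      H_cl <- strokelifetime:::family_cumhaz(cs$family, t, cs$lp, cs$shape)
      expect_equal(H_cl, H_num, tolerance = 1e-6, label = cs$family)
      expect_equal(strokelifetime:::family_surv(cs$family, t, cs$lp, cs$shape),
        exp(-H_num), tolerance = 1e-6)
    }
    expect_equal(strokelifetime:::family_surv(cs$family, 0, cs$lp, cs$shape), 1)
    expect_equal(strokelifetime:::family_cumhaz(cs$family, 0, cs$lp, cs$shape), 0)
  }
})

test_that("Gompertz survival matches its closed form", {
  # lambda = 0.05, gamma = 0.1, t = 10: exp(-(0.05/0.1) * (e^1 - 1))
  s <- strokelifetime:::family_surv("gompertz", 10, log(0.05), 0.1)
  expect_equal(s, exp(-(0.05 / 0.1) * (exp(1) - 1)), tolerance = 1e-12)
  expect_equal(s, 0.4236, tolerance = 1e-3)
})

test_that("log-logistic median equals its scale parameter", {
  # scale 5, gamma 0.5: S(5) = 1/(1 + 1) = 0.5
  expect_equal(strokelifetime:::family_surv("loglogistic", 5, log(5), 0.5), 0.5)
  expect_equal(strokelifetime:::family_quantile("loglogistic", 0.5, log(5), 0.5), 5)
})

test_that("quantile and survival are inverse to 1e-6, all families", {
  for (cs in fam_cases) {
    for (q in c(0.1, 0.5, 0.9)) {
      tq <- strokelifetime:::family_quantile(cs$family, q, cs$lp, cs$shape)
      ## a negative-shape Gompertz is improper: quantiles beyond the
      ## attainable mass are (correctly) infinite
      attainable <- 1 - strokelifetime:::family_surv(cs$family, 1e6, cs$lp, cs$shape)
      if (!is.finite(tq)) {
        expect_gte(q, attainable)
        next
      }
      expect_equal(
        strokelifetime:::family_surv(cs$family, tq, cs$lp, cs$shape),
        1 - q, tolerance = 1e-6, label = paste(cs$family, q)
      )
      ## brute-force inversion oracle on a bracket
      root <- stats::uniroot(function(t) {
        strokelifetime:::family_surv(cs$family, t, cs$lp, cs$shape) - (1 - q)
      }, lower = 1e-10, upper = 1e4, tol = 1e-10)$root
      expect_equal(tq, root, tolerance = 1e-5)
    }
  }
})

test_that("cumulative-hazard inversion is exact (event-stream sampler)", {
  for (cs in fam_cases) {
    for (w in c(0.2, 1, 3)) {
      tt <- strokelifetime:::family_cuminv(cs$family, w, cs$lp, cs$shape)
      if (!is.finite(tt)) { # beyond the total mass of an improper family
        expect_gt(w, strokelifetime:::family_cumhaz(cs$family, 1e6, cs$lp, cs$shape))
        next
      }
      expect_equal(strokelifetime:::family_cumhaz(cs$family, tt, cs$lp, cs$shape),
        w, tolerance = 1e-8, label = cs$family)
    }
  }
})

test_that("Weibull with p = 1 reduces to the exponential", {
  t <- c(0.5, 2, 5)
  expect_equal(
    strokelifetime:::family_cumhaz("weibull", t, log(0.2), 1),
    strokelifetime:::family_cumhaz("exponential", t, log(0.2)),
    tolerance = 1e-12
  )
  # lambda = 0.2, p = 1, t = 5: cumulative hazard = 1
  expect_equal(strokelifetime:::family_cumhaz("weibull", 5, log(0.2), 1), 1)
})

test_that("Gompertz with gamma -> 0 converges to the exponential", {
  t <- c(0.5, 2, 5, 20)
  expect_equal(
    strokelifetime:::family_cumhaz("gompertz", t, log(0.1), 1e-8),
    strokelifetime:::family_cumhaz("exponential", t, log(0.1)),
    tolerance = 1e-5
  )
})

test_that("survival is non-increasing in t for every family", {
  grid <- seq(0, 30, by = 0.1)
  for (cs in fam_cases) {
    s <- strokelifetime:::family_surv(cs$family, grid, cs$lp, cs$shape)
    expect_true(all(diff(s) <= 1e-12), label = cs$family)
    expect_true(all(s >= 0 & s <= 1))
  }
})
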