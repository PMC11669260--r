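# Recurrent-event resource equations on the counting-process scale.

test_that("Weibull intensity parameters are recovered from a simulated ED stream", {
  coh <- simulate_cohort(n = 2500, seed = 88)
  tr <- attr(coh, "truth")
  ev <- expand_events(coh, "ed")
  f <- fit_resource(ev, "weibull")
  truth <- tr$resources$ed
  est <- c(f$coefficients[names(truth$coefficients)], log(f$shape))
  tru <- c(truth$coefficients, log(truth$shape))
  se <- f$se[c(names(truth$coefficients), "shape")]
  ## ED suppression during non-elective stays thins the stream by ~1%, so
  ## allow 3 SE plus that systematic offset on the level
  expect_true(all(abs(est - tru) <= 3 * se + c(0.02, rep(0.01, 7), 0.01)),
    info = paste("est:", toString(round(est, 3)),
      "tru:", toString(round(tru, 3))))
  expect_lt(abs(f$shape / truth$shape - 1), 0.1)
})

test_that("one event per subject reduces to the ordinary single-event fit", {
  set.seed(12)
  n <- 400
  tt <- strokelifetime:::family_rand("weibull", n, log(0.3), 1.2)
  cens <- runif(n, 0.5, 6)
  ## counting-process form: event row then censor row
  rows <- lapply(seq_len(n), function(i) {
    if (tt[i] <= cens[i]) {
      data.frame(start = c(0, tt[i]), stop = c(tt[i], cens[i]),
        event = c(1, 0))
    } else {
      data.frame(start = 0, stop = cens[i], event = 0)
    }
  })
  cp <- do.call(rbind, rows)
  single <- data.frame(start = 0, stop = pmin(tt, cens),
    event = as.numeric(tt <= cens))
  f_single <- surv_mle(single, "weibull")
  ## the first at-risk interval of each subject IS the single-event data:
  ## identical log-likelihood and coefficients
  cp1 <- cp[!(cp$start > 0), ]
  f_cp1 <- surv_mle(cp1, "weibull")
  expect_equal(f_cp1$loglik, f_single$loglik, tolerance = 1e-8)
  expect_equal(coef(f_cp1), coef(f_single), tolerance = 1e-6)
  ## the full counting-process fit additionally sees the event-free
  ## post-event exposure, so it converges but differs
  f_cp <- surv_mle(cp, "weibull")
  expect_true(f_cp$converged)
})

test_that("a stream with no failures is refused", {
  df <- data.frame(id = "a", age = 70, sex = "female", mrs = 1,
    followup_days = 1000, died = 0)
  ev <- expand_events(as_stroke_cohort(df), "elective_bed_days")
  expect_error(fit_resource(ev, "loglogistic"), "no resource-use failures")
})

test_that("expected counts match closed forms and a Monte-Carlo oracle", {
  d <- data.frame(start = 0, stop = rexp(500, 0.5) + 1e-5, event = 1,
    age = 0, male = 0, mrs1 = 0, mrs2 = 0, mrs3 = 0, mrs4 = 0, mrs5 = 0)
  f <- surv_mle(d, "weibull", ~ age + male + mrs1 + mrs2 + mrs3 + mrs4 + mrs5)
  names(f$coefficients)[1] <- "intercept"
  prof <- data.frame(age = 73.69, sex = "female", mrs = 0)
  expect_equal(unname(expected_count(f, prof, 0)), 0)
  ## force known parameters: rate 0.5/yr, p = 1 -> 2 events by t = 4
  f$coefficients[] <- c(log(0.5), rep(0, 7))
  f$shape <- 1
  expect_equal(unname(expected_count(f, prof, 4)), 2, tolerance = 1e-10)
  ## Monte-Carlo oracle for a log-logistic intensity
  lp <- log(0.4)
  gam <- 0.5
  m <- strokelifetime:::family_cumhaz("loglogistic", 5, lp, gam)
  set.seed(44)
  counts <- rpois(2e4, m) # exact distribution of the inhomogeneous stream
  expect_lt(abs(mean(counts) / m - 1), 0.02)
  sim <- replicate(2000, length(strokelifetime:::rpoisproc("loglogistic", lp, gam, 5)))
  expect_lt(abs(mean(sim) / m - 1), 0.05)
})

test_that("family comparison on a resource stream is deterministic and ranks truth first", {
  coh <- simulate_cohort(n = 1200, seed = 19)
  ev <- expand_events(coh, "nonelective_bed_days")
  tab1 <- compare_resource_families(ev, families = c("weibull", "loglogistic", "gompertz"))
  tab2 <- compare_resource_families(ev, families = c("weibull", "loglogistic", "gompertz"))
  expect_identical(tab1$family, tab2$family)
  expect_equal(tab1$family[1], "loglogistic") # the generating family
})

test_that("fitted sex effects reproduce the derivation pattern qualitatively", {
  coh <- simulate_cohort(n = 2000, seed = 23)
  ed <- fit_resource(expand_events(coh, "ed"), "weibull")
  expect_lt(ed$coefficients[["male"]], 0) # men attend ED less
  el <- fit_resource(expand_events(coh, "elective_bed_days"), "loglogistic")
  expect_lt(el$coefficients[["male"]], 0) # AFT scale: lower = more use
})
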