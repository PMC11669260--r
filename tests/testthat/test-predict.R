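# The prediction engine: composed survival, life expectancy, lifetime
# resource counts, economics, comparisons, dichotomized variant.

ref <- reference_model()

test_that("the composed curve is a valid survival function for all profiles", {
  for (mrs in c(0, 2, 5)) {
    for (age in c(50, 73.69, 95)) {
      pr <- data.frame(age = age, sex = "male", mrs = mrs)
      sc <- survival_curve(ref, pr, grid_step = 0.1)
      expect_equal(sc$surv[1], 1)
      expect_true(all(diff(sc$surv) <= 1e-10))
      expect_true(all(sc$surv >= 0 & sc$surv <= 1))
      ## forced to zero at the age-100 horizon
      expect_equal(sc$surv[nrow(sc)], 0)
    }
  }
})

test_that("composition agrees with the brute-force annual recursion", {
  pr <- data.frame(age = 73.69, sex = "female", mrs = 1)
  S <- survival_function(ref, pr)
  p1 <- year1_death_prob(ref, pr)
  lt_eq <- ref$mortality$lifetime
  lp <- strokelifetime:::eval_lp(lt_eq, strokelifetime:::check_profile(ref, pr),
    ref$centering_mean, ref$states)
  sg <- function(t) strokelifetime:::family_surv("gompertz", t, lp, lt_eq$shape)
  ## annual recursion: yearly conditional death probabilities multiplied out
  s_rec <- 1 - p1
  for (yr in 2:10) {
    q_yr <- 1 - sg(yr) / sg(yr - 1)
    s_rec <- s_rec * (1 - q_yr)
    expect_lt(abs(S(yr) - s_rec), 0.005)
  }
})

test_that("median life expectancy solves S = 0.5 and caps at the horizon", {
  pr <- data.frame(age = 65, sex = "female", mrs = 1)
  le <- median_le(ref, pr)
  S <- survival_function(ref, pr)
  expect_equal(S(le$median), 0.5, tolerance = 1e-6)
  expect_equal(S(le$q25), 0.75, tolerance = 1e-6)
  expect_true(le$q25 < le$median && le$median < le$q75)
  ## degenerate: no year-1 risk, negligible lifetime hazard -> capped
  degen <- ref
  degen$mortality$year1$coefficients[] <- 0
  degen$mortality$year1$coefficients["intercept"] <- -30
  degen$mortality$lifetime$coefficients["intercept"] <- -30
  le2 <- median_le(degen, pr)
  expect_equal(le2$median, 100 - 65)
  expect_true(le2$capped[["median"]])
})

test_that("median life expectancy is monotone in mRS and age", {
  for (sex in c("female", "male")) {
    med_by_mrs <- vapply(0:5, function(m) {
      median_le(ref, data.frame(age = 73.69, sex = sex, mrs = m))$median
    }, 0)
    expect_true(all(diff(med_by_mrs) < 0))
    med_by_age <- vapply(c(55, 65, 75, 85), function(a) {
      median_le(ref, data.frame(age = a, sex = sex, mrs = 2))$median
    }, 0)
    expect_true(all(diff(med_by_age) < 0))
  }
})

test_that("lifetime counts: quadrature matches Monte-Carlo within 2%", {
  pr <- data.frame(age = 75, sex = "male", mrs = 3)
  counts <- lifetime_resource_use(ref, pr, method = "integral")
  S <- survival_function(ref, pr)
  eq <- ref$resources$ed
  lp <- strokelifetime:::eval_lp(eq, strokelifetime:::check_profile(ref, pr),
    ref$centering_mean, ref$states)
  ## Monte-Carlo oracle: sample a lifetime from the composed curve by
  ## inverse transform on a fine grid, then count events up to it
  set.seed(31)
  grid <- seq(0, 100 - 75, by = 0.005)
  sv <- S(grid)
  u <- runif(2e4)
  life <- grid[findInterval(-u, -sv) + 1] # first t with S(t) <= u
  m <- strokelifetime:::family_cumhaz(eq$family, life, lp, eq$shape)
  mc <- mean(m) # E[N] = E[Lambda(T)] for the Poisson stream
  expect_lt(abs(counts[["ed"]] / mc - 1), 0.02)
})

test_that("zero-intensity resources yield zero lifetime counts", {
  z <- ref
  for (nm in names(z$resources)) {
    ## zero intensity: rate -> 0 for the PH-metric Weibull (intercept -> -Inf),
    ## scale -> Inf for the AFT-metric log-logistic (intercept -> +Inf)
    z$resources[[nm]]$coefficients["intercept"] <-
      if (z$resources[[nm]]$family == "weibull") -40 else 40
  }
  counts <- lifetime_resource_use(z, data.frame(age = 70, sex = "female", mrs = 2),
    method = "integral")
  expect_true(all(counts < 1e-10))
})

test_that("both lifetime-count conventions are available and recorded", {
  pr <- data.frame(age = 65, sex = "female", mrs = 1)
  a <- lifetime_resource_use(ref, pr, method = "integral")
  b <- lifetime_resource_use(ref, pr, method = "at_median")
  expect_equal(attr(a, "method"), "integral")
  expect_equal(attr(b, "method"), "at_median")
  expect_false(isTRUE(all.equal(a[["ed"]], b[["ed"]])))
})

test_that("economics reduces to life expectancy under degenerate settings", {
  z <- ref
  for (nm in names(z$resources)) {
    ## zero intensity: rate -> 0 for the PH-metric Weibull (intercept -> -Inf),
    ## scale -> Inf for the AFT-metric log-logistic (intercept -> +Inf)
    z$resources[[nm]]$coefficients["intercept"] <-
      if (z$resources[[nm]]$family == "weibull") -40 else 40
  }
  z$economics$utilities[] <- 1
  pr <- data.frame(age = 80, sex = "male", mrs = 2)
  ec <- economics(z, pr, discount_rate = 0)
  expect_equal(ec$qalys, ec$life_expectancy, tolerance = 1e-6)
  expect_lt(ec$cost, 1e-6)
  ## area under the survival curve, independent oracle
  S <- survival_function(z, pr)
  auc <- stats::integrate(S, 0, 1, rel.tol = 1e-9)$value +
    stats::integrate(S, 1, 20, rel.tol = 1e-9)$value
  expect_equal(ec$life_expectancy, auc, tolerance = 1e-5)
})

test_that("discounting strictly reduces costs and QALYs, more so for longer lives", {
  young <- data.frame(age = 60, sex = "female", mrs = 1)
  old <- data.frame(age = 88, sex = "female", mrs = 1)
  for (pr in list(young, old)) {
    e0 <- economics(ref, pr, discount_rate = 0)
    e35 <- economics(ref, pr, discount_rate = 0.035)
    expect_lt(e35$cost, e0$cost)
    expect_lt(e35$qalys, e0$qalys)
  }
  gap <- function(pr) {
    1 - economics(ref, pr, discount_rate = 0.035)$qalys /
      economics(ref, pr, discount_rate = 0)$qalys
  }
  expect_gt(gap(young), gap(old))
})

test_that("unit costs are carried through verbatim", {
  ec <- economics(ref, data.frame(age = 70, sex = "female", mrs = 1))
  expect_equal(unname(ec$unit_costs["ed_attendance"]), 137)
  expect_equal(unname(ec$unit_costs["nonelective_bed_day"]), 533)
  expect_equal(unname(ec$unit_costs["elective_bed_day"]), 444)
  expect_equal(ec$currency, "GBP")
})

test_that("identical profiles compare to all-zero deltas", {
  pr <- data.frame(age = 70, sex = "male", mrs = 2)
  cmp <- compare_profiles(ref, pr, pr)
  expect_true(all(abs(cmp$delta) < 1e-10))
})

test_that("dichotomized mapping and mode separation", {
  dd <- dichotomize_model(ref)
  expect_identical(dd$states, c("independent", "dependent"))
  ## mRS 0 maps to the independent state deterministically
  p0 <- predict(dd, data.frame(age = 70, sex = "female", mrs = 0),
    economics = FALSE)
  pi <- predict(dd, data.frame(age = 70, sex = "female", state = "independent"),
    economics = FALSE)
  expect_equal(p0$median_le, pi$median_le)
  ## dependent patients fare worse at matched age and sex
  pd <- predict(dd, data.frame(age = 70, sex = "female", state = "dependent"),
    economics = FALSE)
  expect_lt(pd$median_le, pi$median_le)
  ## six-level model refuses a state profile; the two modes differ
  expect_error(
    predict(ref, data.frame(age = 70, sex = "female", state = "independent")),
    "six mRS states"
  )
  p_six <- predict(ref, data.frame(age = 70, sex = "female", mrs = 1),
    economics = FALSE)
  p_two <- predict(dd, data.frame(age = 70, sex = "female", mrs = 1),
    economics = FALSE)
  expect_false(isTRUE(all.equal(p_six$median_le, p_two$median_le)))
})

test_that("profiles beyond the life-table support are errors", {
  expect_error(survival_curve(ref, data.frame(age = 101, sex = "male", mrs = 1)),
    "\\[0, 100\\]")
  expect_error(median_le(ref, data.frame(age = 100, sex = "male", mrs = 1)),
    "horizon")
  expect_error(survival_curve(ref, data.frame(age = 70, sex = "male", mrs = 7)),
    "0-5")
})
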