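# Shared fixtures, built once per test run.

# pure-Gompertz synthetic life table (the recovery-consistent configuration)
fix_lt <- synthetic_life_table()

# small cohort from the cohort-emulation truth, reused across tests
fix_cohort <- simulate_cohort(n = 600, seed = 42)

# single-event survival data from a known Gompertz, with censoring
make_gompertz_data <- function(n, seed, lp0 = -2, beta = 0.4, gamma = 0.12,
                               cens = c(1, 8)) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  tt <- strokelifetime:::family_rand("gompertz", n, lp0 + beta * x, gamma)
  cn <- stats::runif(n, cens[1], cens[2])
  data.frame(start = 0, stop = pmin(tt, cn), event = as.numeric(tt <= cn), x = x)
}

# a tiny hand-written three-patient cohort exercising every event field
make_toy_cohort <- function() {
  df <- data.frame(
    id = c("a", "b", "c"),
    age = c(70, 80, 65),
    sex = c("female", "male", "female"),
    mrs = c(1, 3, 0),
    followup_days = c(100, 400, 2000),
    died = c(0, 1, 0)
  )
  df$ed_days <- list(c(12L, 50L), integer(0), c(5L, 300L))
  df$nonelective_stays <- list(
    matrix(c(10, 15), 1, 2), matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2)
  )
  df$elective_stays <- list(
    matrix(numeric(0), 0, 2), matrix(c(30, 3), 1, 2), matrix(numeric(0), 0, 2)
  )
  as_stroke_cohort(df)
}
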