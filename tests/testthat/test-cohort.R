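# Cohort validation, CSV round-trip, and the counting-process expansion
# of recurrent events.

test_that("records with missing mRS are excluded and counted", {
  df <- data.frame(
    id = letters[1:10], age = 70, sex = "female",
    mrs = c(1, 2, NA, 3, NA, 0, 5, 4, 2, 1),
    followup_days = 1000, died = 0
  )
  expect_message(coh <- as_stroke_cohort(df), "2 record")
  expect_equal(nrow(coh), 8)
  expect_equal(attr(coh, "n_excluded"), 2)
})

test_that("event histories beyond follow-up are validation errors", {
  df <- data.frame(id = "a", age = 70, sex = "f", mrs = 1,
    followup_days = 100, died = 0)
  df$ed_days <- list(c(50L, 150L))
  expect_error(as_stroke_cohort(df), "record 'a'")
  df$ed_days <- list(integer(0))
  df$nonelective_stays <- list(matrix(c(10, 0.5), 1, 2))
  expect_error(as_stroke_cohort(df), "length below 1")
})

test_that("an empty cohort is an error, not an empty object", {
  expect_error(as_stroke_cohort(data.frame()), "missing columns|empty")
  path <- tempfile(fileext = ".csv")
  writeLines("id,age,sex,mrs,followup_days,died", path)
  expect_error(read_cohort(path), "no records")
})

test_that("cohort CSV round-trip preserves all event histories", {
  coh <- make_toy_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  coh2 <- read_cohort(path)
  expect_equal(coh2$age, coh$age)
  expect_equal(coh2$ed_days, coh$ed_days)
  expect_equal(coh2$nonelective_stays, coh$nonelective_stays)
  expect_equal(coh2$elective_stays, coh$elective_stays)
})

test_that("malformed event strings report the offending row", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,age,sex,mrs,followup_days,died,ed_days,nonelective_stays,elective_stays",
    "a,70,female,1,100,0,12;xx,,"
  ), path)
  expect_error(read_cohort(path), "row 1")
})

test_that("a 15-day non-elective stay expands to 15 daily failures plus a censor row", {
  df <- data.frame(id = "p", age = 70, sex = "female", mrs = 2,
    followup_days = 100, died = 0)
  df$nonelective_stays <- list(matrix(c(10, 15), 1, 2))
  coh <- as_stroke_cohort(df)
  ev <- expand_events(coh, "nonelective_bed_days")
  expect_equal(sum(ev$event), 15)
  expect_equal(nrow(ev), 16)
  expect_equal(ev$stop[nrow(ev)], 100 / 365.25)
  expect_equal(ev$event[nrow(ev)], 0)
  ## rows partition [0, followup]: starts chain to stops, strictly increasing
  expect_equal(ev$start[-1], ev$stop[-nrow(ev)])
  expect_true(all(diff(ev$stop) > 0))
  expect_equal(ev$start[1], 0)
})

test_that("ED attendances during a non-elective stay are suppressed", {
  df <- data.frame(id = "p", age = 70, sex = "female", mrs = 2,
    followup_days = 100, died = 0)
  df$ed_days <- list(12L) # inside the stay spanning days 10-24
  df$nonelective_stays <- list(matrix(c(10, 15), 1, 2))
  coh <- as_stroke_cohort(df)
  ev <- expand_events(coh, "ed")
  expect_equal(sum(ev$event), 0)
  ## the day after the stay ends is counted
  df$ed_days <- list(25L)
  ev2 <- expand_events(as_stroke_cohort(df), "ed")
  expect_equal(sum(ev2$event), 1)
})

test_that("a patient with no events contributes a single censored row", {
  df <- data.frame(id = "p", age = 70, sex = "male", mrs = 0,
    followup_days = 500, died = 1)
  ev <- expand_events(as_stroke_cohort(df), "ed")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event, 0)
  expect_equal(ev$start, 0)
  expect_equal(ev$stop, 500 / 365.25)
})

test_that("expansion conserves event counts on a simulated cohort", {
  coh <- fix_cohort
  ne <- expand_events(coh, "nonelective_bed_days")
  expect_equal(sum(ne$event),
    sum(vapply(coh$nonelective_stays, function(m) sum(m[, 2]), 0)))
  el <- expand_events(coh, "elective_bed_days")
  expect_equal(sum(el$event),
    sum(vapply(coh$elective_stays, function(m) sum(m[, 2]), 0)))
  ## ED: totals minus the suppressed attendance days
  suppressed <- sum(vapply(seq_len(nrow(coh)), function(i) {
    d <- coh$ed_days[[i]]
    st <- coh$nonelective_stays[[i]]
    if (!length(d) || !nrow(st)) return(0L)
    sum(vapply(d, function(dd) any(dd >= st[, 1] & dd < st[, 1] + st[, 2]), NA))
  }, 0L))
  ed <- expand_events(coh, "ed")
  expect_equal(sum(ed$event), sum(lengths(coh$ed_days)) - suppressed)
  ## per-subject intervals partition [0, followup] without overlap
  one <- ed[ed$id == coh$id[which(lengths(coh$ed_days) > 2)[1]], ]
  expect_equal(one$start[-1], one$stop[-nrow(one)])
})
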