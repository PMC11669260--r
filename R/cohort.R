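#' Stroke cohort data model
#'
#' A cohort is a data frame of one row per patient with columns:
#' `id`, `age` (age at stroke onset, years), `sex` (`"female"`/`"male"`),
#' `mrs` (modified Rankin Scale at discharge, integer 0–5, `NA` when
#' missing), `followup_days` (days from discharge to death or censoring),
#' `died` (0/1), and three list-columns holding the secondary-care event
#' history: `ed_days` (integer vector of attendance days since discharge),
#' `nonelective_stays` and `elective_stays` (two-column matrices
#' `start_day`, `length_days`, one row per stay).
#'
#' `as_stroke_cohort()` validates such a data frame, drops records with
#' missing mRS (assumed missing at random, as in the source cohort design)
#' and records the number excluded in attribute `"n_excluded"`.
#'
#' @param df data frame as described above.
#' @return a validated `"stroke_cohort"` data frame.
#' @export
as_stroke_cohort <- function(df) {
  need <- c("id", "age", "sex", "mrs", "followup_days", "died")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort is missing columns: ", toString(miss))
  if (nrow(df) == 0) stop("cohort is empty")
  for (col in c("ed_days", "nonelective_stays", "elective_stays")) {
    if (is.null(df[[col]])) {
      df[[col]] <- replicate(nrow(df), integer(0), simplify = FALSE)
    }
  }
  df$sex <- check_sex(df$sex)
  bad <- which(!is.na(df$mrs) & !(df$mrs %in% 0:5))
  if (length(bad)) stop("mRS outside 0-5 in row(s): ", toString(utils::head(bad, 10)))
  bad <- which(is.na(df$age) | df$age < 0 | df$age > 100)
  if (length(bad)) stop("age outside life-table support in row(s): ", toString(utils::head(bad, 10)))
  bad <- which(is.na(df$followup_days) | df$followup_days < 0)
  if (length(bad)) stop("negative or missing follow-up in row(s): ", toString(utils::head(bad, 10)))

  for (i in seq_len(nrow(df))) {
    fu <- df$followup_days[i]
    ed <- df$ed_days[[i]]
    if (length(ed) && (any(ed < 0) || any(ed > fu))) {
      stop("record '", df$id[i], "': ED attendance day outside [0, follow-up]")
    }
    for (col in c("nonelective_stays", "elective_stays")) {
      st <- stay_matrix(df[[col]][[i]])
      df[[col]][[i]] <- st
      if (nrow(st)) {
        if (any(st[, 2] < 1)) {
          stop("record '", df$id[i], "': stay length below 1 day")
        }
        if (any(st[, 1] < 0) || any(st[, 1] > fu)) {
          stop("record '", df$id[i], "': stay start day outside [0, follow-up]")
        }
      }
    }
  }
  n_excl <- sum(is.na(df$mrs))
  if (n_excl > 0) {
    message("excluding ", n_excl, " record(s) with missing discharge mRS")
    df <- df[!is.na(df$mrs), , drop = FALSE]
    if (nrow(df) == 0) stop("all records have missing mRS")
  }
  rownames(df) <- NULL
  attr(df, "n_excluded") <- n_excl
  class(df) <- c("stroke_cohort", "data.frame")
  df
}

stay_matrix <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start_day", "length_days"))))
  }
  m <- if (is.matrix(x)) x else matrix(x, ncol = 2, byrow = TRUE)
  colnames(m) <- c("start_day", "length_days")
  m
}

#' Read / write a cohort CSV
#'
#' The flat CSV encoding stores the event lists as delimited strings:
#' `ed_days` as semicolon-separated days (`"12;45;300"`),
#' `nonelective_stays` and `elective_stays` as semicolon-separated
#' `start:length` pairs (`"10:15;200:3"`). Empty strings mean no events.
#' Records with missing `mrs` are excluded (missing-at-random assumption)
#' and counted in attribute `"n_excluded"`.
#'
#' @param path CSV path.
#' @return `read_cohort()`: a `"stroke_cohort"`; `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  cls <- intersect(c("ed_days", "nonelective_stays", "elective_stays"), header)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = stats::setNames(as.list(rep("character", length(cls))), cls))
  if (nrow(df) == 0) stop("cohort file '", path, "' contains no records")
  parse_days <- function(s, row) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    v <- suppressWarnings(as.integer(strsplit(s, ";", fixed = TRUE)[[1]]))
    if (any(is.na(v))) stop("malformed ed_days in data row ", row, ": '", s, "'")
    v
  }
  parse_stays <- function(s, row, col) {
    if (is.na(s) || !nzchar(s)) return(stay_matrix(NULL))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop("malformed ", col, " in data row ", row, ": '", s, "'")
    }
    m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE))
    if (any(is.na(m))) stop("malformed ", col, " in data row ", row, ": '", s, "'")
    stay_matrix(m)
  }
  n <- nrow(df)
  df$ed_days <- lapply(seq_len(n), function(i) parse_days(df$ed_days[i] %||% NA, i))
  df$nonelective_stays <- lapply(seq_len(n), function(i) {
    parse_stays(df$nonelective_stays[i] %||% NA, i, "nonelective_stays")
  })
  df$elective_stays <- lapply(seq_len(n), function(i) {
    parse_stays(df$elective_stays[i] %||% NA, i, "elective_stays")
  })
  as_stroke_cohort(df)
}

#' @rdname read_cohort
#' @param cohort a `"stroke_cohort"`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "stroke_cohort"))
  fmt_days <- function(v) paste(v, collapse = ";")
  fmt_stays <- function(m) paste(sprintf("%g:%g", m[, 1], m[, 2]), collapse = ";")
  out <- data.frame(
    id = cohort$id, age = cohort$age, sex = cohort$sex, mrs = cohort$mrs,
    followup_days = cohort$followup_days, died = cohort$died,
    ed_days = vapply(cohort$ed_days, fmt_days, character(1)),
    nonelective_stays = vapply(cohort$nonelective_stays, fmt_stays, character(1)),
    elective_stays = vapply(cohort$elective_stays, fmt_stays, character(1))
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.stroke_cohort <- function(x, ...) {
  cat(sprintf(
    "Stroke cohort: %d patients (%d excluded for missing mRS)\n",
    nrow(x), attr(x, "n_excluded") %||% 0L
  ))
  cat(sprintf(
    "  mean age %.1f, male %.0f%%, died %.0f%%, median follow-up %.0f days\n",
    mean(x$age), 100 * mean(x$sex == "male"), 100 * mean(x$died),
    stats::median(x$followup_days)
  ))
  invisible(x)
}

DAYS_PER_YEAR <- 365.25

#' Counting-process expansion of recurrent secondary-care events
#'
#' Expands a cohort into the event table used to fit the resource
#' equations. Every occurrence of resource use becomes a "failure" on the
#' total-time-since-discharge scale with delayed entry: attendances are one
#' failure per attendance day; admissions are one failure per occupied bed
#' day (a 15-day stay contributes 15 sequential daily failures). ED
#' attendances that fall inside a non-elective stay (any day in
#' `[start, start + length)`) are suppressed — they are part of the
#' admission, not a separate contact. Each patient's rows partition
#' `[0, followup]`; the final row is censored at follow-up. Follow-up ends
#' at death or administrative censoring, whichever comes first (death is
#' treated as censoring for the resource processes).
#'
#' Event times are placed strictly inside their day (k events on day `d`
#' sit at `d + j/(k+1)` days) so stop times are strictly increasing within
#' a patient and the delayed-entry likelihood is well defined.
#'
#' @param cohort a `"stroke_cohort"`.
#' @param stream `"ed"`, `"nonelective_bed_days"` or `"elective_bed_days"`.
#' @param centering_mean age (years) subtracted from `age` to form the
#'   centered covariate `age_c` (default the cohort-model convention,
#'   73.69).
#' @return data frame with columns `id`, `start`, `stop` (years), `event`
#'   (0/1), `age`, `age_c`, `sex`, `male`, `mrs` (factor 0–5), of class
#'   `"event_table"`.
#' @export
expand_events <- function(cohort, stream = c("ed", "nonelective_bed_days", "elective_bed_days"),
                          centering_mean = 73.69) {
  stopifnot(inherits(cohort, "stroke_cohort"))
  stream <- match.arg(stream)
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    fu_days <- cohort$followup_days[i]
    days <- switch(stream,
      ed = {
        d <- cohort$ed_days[[i]]
        ne <- cohort$nonelective_stays[[i]]
        if (length(d) && nrow(ne)) {
          inside <- vapply(d, function(dd) {
            any(dd >= ne[, 1] & dd < ne[, 1] + ne[, 2])
          }, logical(1))
          d <- d[!inside]
        }
        d
      },
      nonelective_bed_days = stay_days(cohort$nonelective_stays[[i]], fu_days),
      elective_bed_days = stay_days(cohort$elective_stays[[i]], fu_days)
    )
    times <- numeric(0)
    if (length(days)) {
      days <- sort(days)
      off <- stats::ave(days, days, FUN = function(v) seq_along(v) / (length(v) + 1))
      times <- (days + off) / DAYS_PER_YEAR
    }
    fu <- fu_days / DAYS_PER_YEAR
    times <- times[times < fu]
    stops <- c(times, fu)
    if (fu <= 0 && !length(times)) next
    rows[[i]] <- data.frame(
      id = cohort$id[i],
      start = c(0, utils::head(stops, -1)),
      stop = stops,
      event = c(rep(1, length(times)), 0),
      age = cohort$age[i], sex = cohort$sex[i], mrs = cohort$mrs[i]
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no at-risk time in cohort")
  out$age_c <- out$age - centering_mean
  out$male <- as.numeric(out$sex == "male")
  out$mrs <- factor(out$mrs, levels = 0:5)
  attr(out, "stream") <- stream
  attr(out, "centering_mean") <- centering_mean
  class(out) <- c("event_table", "data.frame")
  out
}

## occupied days of all stays, clipped to follow-up
stay_days <- function(stays, fu_days) {
  if (!nrow(stays)) return(integer(0))
  unlist(lapply(seq_len(nrow(stays)), function(j) {
    d <- seq(stays[j, 1], length.out = stays[j, 2])
    d[d <= fu_days]
  }))
}
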