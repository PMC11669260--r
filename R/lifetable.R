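#' Life tables: the general-population mortality backbone
#'
#' A life table holds the annual probability of death `qx` (probability of
#' dying before age `x + 1` conditional on being alive at age `x`) for
#' integer ages 0–100 and both sexes. It drives the synthetic
#' general-population control cohort in the first simulation stage and the
#' imputation of death dates for patients still alive at censoring in the
#' second stage. Lifespan is truncated at 100 years: a person reaching age
#' 100 alive is assigned a death uniformly within [100, 101).
#'
#' @param data data frame with columns `age` (integer 0–100), `sex`
#'   (`"female"`/`"male"`) and `qx` in `[0, 1]`, one row per age and sex.
#' @return an object of class `"life_table"`: a list with matrix `qx`
#'   (101 ages x 2 sexes).
#' @seealso [read_life_table()], [synthetic_life_table()],
#'   [sample_death_age()]
#' @export
life_table <- function(data) {
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(data))) {
    stop("life table needs columns: ", toString(setdiff(need, names(data))))
  }
  data$sex <- check_sex(data$sex)
  if (any(data$qx < 0 | data$qx > 1 | !is.finite(data$qx))) {
    stop("life-table qx values must lie in [0, 1]")
  }
  qx <- matrix(NA_real_, nrow = 101, ncol = 2,
    dimnames = list(0:100, c("female", "male")))
  for (s in c("female", "male")) {
    rows <- data[data$sex == s, ]
    qx[as.character(rows$age), s] <- rows$qx
    gaps <- (0:100)[is.na(qx[, s])]
    if (length(gaps)) {
      stop("life table is missing ", s, " entries for age(s): ",
        toString(utils::head(gaps, 10)))
    }
  }
  structure(list(qx = qx), class = "life_table")
}

#' @rdname life_table
#' @param path CSV file with columns `age,sex,qx` covering ages 0–100 for
#'   both sexes.
#' @export
read_life_table <- function(path) {
  life_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname life_table
#' @param lt a `"life_table"` object.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  df <- data.frame(
    age = rep(0:100, 2),
    sex = rep(c("female", "male"), each = 101),
    ## full binary precision so a written table reloads bit-identically
    qx = sprintf("%.17g", c(lt$qx[, "female"], lt$qx[, "male"]))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table: ages 0-100, female & male\n")
  cat(sprintf(
    "  q65 (F/M): %.4f / %.4f   q85 (F/M): %.4f / %.4f\n",
    x$qx["65", "female"], x$qx["65", "male"],
    x$qx["85", "female"], x$qx["85", "male"]
  ))
  invisible(x)
}

check_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "0")] <- "female"
  s[s %in% c("m", "1")] <- "male"
  if (!all(s %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  s
}

#' Parametric synthetic life table (Gompertz–Makeham hazard)
#'
#' Builds a life table from the Gompertz–Makeham force of mortality
#' `mu(x) = a + b * exp(c * x)`:
#' `qx = 1 - exp(-integral of mu over [x, x+1])`, with the closed-form
#' integral `a + (b/c) * (exp(c*(x+1)) - exp(c*x))`. Sex-specific `b`
#' allows a male–female mortality gap. With `a = 0` the hazard is pure
#' Gompertz, which makes the table exactly consistent with a Gompertz
#' survival equation whose age coefficient equals `c` — the configuration
#' used by the package's parameter-recovery simulations.
#'
#' @param a Makeham (age-independent) hazard, `>= 0`.
#' @param b Gompertz level at age 0 (per year, `> 0`); scalar or named
#'   vector `c(female=, male=)`.
#' @param c exponential age slope (per year, `>= 0`).
#' @return a `"life_table"` object.
#' @examples
#' lt <- synthetic_life_table()
#' lt$qx["80", ]
#' @export
synthetic_life_table <- function(a = 0, b = c(female = 2.2e-05, male = 3.2e-05),
                                 c = 0.095) {
  if (a < 0 || any(b <= 0) || c < 0) {
    stop("require a >= 0, b > 0, c >= 0")
  }
  if (length(b) == 1) b <- stats::setNames(rep(b, 2), c("female", "male"))
  ages <- 0:100
  qx_of <- function(bb) {
    cumh <- if (c == 0) a + bb else a + (bb / c) * (exp(c * (ages + 1)) - exp(c * ages))
    pmin(pmax(1 - exp(-cumh), 0), 1)
  }
  life_table(data.frame(
    age = rep(ages, 2),
    sex = rep(c("female", "male"), each = 101),
    qx = c(qx_of(b[["female"]]), qx_of(b[["male"]]))
  ))
}

#' Sample an age at death from a life table
#'
#' Walks the life table one year at a time from `current_age`, converting
#' each annual death probability to a hazard scaled by the hazard ratio
#' (`q' = 1 - (1 - qx)^hr`, exact for proportional hazards on the
#' within-year scale), drawing a Bernoulli death indicator per year and
#' placing the death uniformly within the death year. Anyone reaching age
#' 100 alive is assigned a death uniformly within [100, 101) (the life
#' table carries no information beyond 100).
#'
#' Vectorized over `current_age`, `sex` and `hr`.
#'
#' @param lt a `"life_table"`.
#' @param current_age age(s) in years, `<= 100` (fractional allowed; the
#'   first partial year uses the current integer age's qx over the
#'   remaining fraction of the year).
#' @param sex `"female"`/`"male"`, recycled.
#' @param hr hazard ratio(s) `>= 0` versus the general population (1 for
#'   population controls).
#' @param n number of draws when the inputs are scalar.
#' @return numeric vector of fractional ages at death, in (current_age, 101).
#' @export
sample_death_age <- function(lt, current_age, sex, hr = 1, n = NULL) {
  stopifnot(inherits(lt, "life_table"))
  if (any(current_age > 100)) stop("current_age must be <= 100")
  if (any(hr < 0)) stop("hazard ratio must be >= 0")
  m <- max(length(current_age), length(sex), length(hr), n %||% 1L)
  age <- rep_len(as.numeric(current_age), m)
  sexi <- rep_len(match(check_sex(sex), c("female", "male")), m)
  hr <- rep_len(as.numeric(hr), m)

  out <- rep(NA_real_, m)
  alive <- rep(TRUE, m)
  cur <- age
  ## first (possibly partial) year, then whole years to the age-100 cap
  for (step in seq_len(103)) {
    idx <- which(alive)
    if (!length(idx)) break
    a_int <- pmin(floor(cur[idx]), 100)
    at_cap <- cur[idx] >= 100
    frac <- ifelse(floor(cur[idx]) == cur[idx], 1, ceiling(cur[idx]) - cur[idx])
    q <- lt$qx[cbind(a_int + 1, sexi[idx])]
    ## annual hazard scaled by hr, applied over the remaining year fraction
    qeff <- 1 - exp(log1p(-pmin(q, 1 - 1e-12)) * hr[idx] * frac)
    u <- stats::runif(length(idx))
    dies <- u < qeff | at_cap
    died_idx <- idx[dies]
    if (length(died_idx)) {
      span <- ifelse(cur[died_idx] >= 100, 1,
        ifelse(floor(cur[died_idx]) == cur[died_idx], 1,
          ceiling(cur[died_idx]) - cur[died_idx]))
      out[died_idx] <- pmin(cur[died_idx], 100) +
        stats::runif(length(died_idx)) * span
      alive[died_idx] <- FALSE
    }
    surv_idx <- idx[!dies]
    cur[surv_idx] <- ifelse(floor(cur[surv_idx]) == cur[surv_idx],
      cur[surv_idx] + 1, ceiling(cur[surv_idx]))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
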