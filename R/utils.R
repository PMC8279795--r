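# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded operations never
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

is_leap_year <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

date_parts <- function(d) {
  lt <- as.POSIXlt(d)
  list(year = lt$year + 1900L, month = lt$mon + 1L, day = lt$mday)
}

#' Shift a date by whole calendar months, clamping the day of month
#' (e.g. Jan 31 minus 3 months is Oct 31; Mar 31 minus 1 month is Feb 28/29).
#' @noRd
shift_months <- function(d, months) {
  p <- date_parts(d)
  m0 <- p$year * 12L + (p$month - 1L) + as.integer(months)
  y <- m0 %/% 12L
  m <- m0 %% 12L + 1L
  dim <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m]
  dim <- ifelse(m == 2L & is_leap_year(y), 29L, dim)
  as.Date(sprintf("%04d-%02d-%02d", y, m, pmin(p$day, dim)))
}

shift_years <- function(d, years) shift_months(d, 12L * as.integer(years))

#' Completed years of age at an anchor date
#'
#' Whole years elapsed between \code{birth_date} and \code{anchor}; a year is
#' not complete until the birthday is reached. A February 29 birthday
#' completes its year on February 28 in non-leap years.
#'
#' @param birth_date Date (or coercible) vector of birth dates.
#' @param anchor Date (or coercible) anchor; recycled against
#'   \code{birth_date}.
#' @return Integer vector of completed years.
#' @examples
#' age_on(as.Date("2000-07-01"), as.Date("2018-06-30"))  # 17
#' age_on(as.Date("2000-02-29"), as.Date("2018-02-28"))  # 18
#' @export
age_on <- function(birth_date, anchor) {
  birth_date <- as.Date(birth_date)
  anchor <- as.Date(anchor)
  n <- max(length(birth_date), length(anchor))
  birth_date <- rep_len(birth_date, n)
  anchor <- rep_len(anchor, n)
  if (any(anchor < birth_date)) {
    stop("anchor date precedes birth date")
  }
  b <- date_parts(birth_date)
  a <- date_parts(anchor)
  bd <- ifelse(b$month == 2L & b$day == 29L & !is_leap_year(a$year), 28L, b$day)
  reached <- (a$month > b$month) | (a$month == b$month & a$day >= bd)
  as.integer(a$year - b$year - !reached)
}

#' Measurement period
#'
#' The closed date interval over which measures are evaluated; the default is
#' the 2018 calendar year.
#'
#' @param start,end Dates (or coercible strings) with \code{start <= end}.
#' @return An object of class \code{fqm_period} with elements \code{start},
#'   \code{end} and \code{mid} (the interval midpoint, used by diagnosis
#'   cutoffs anchored at mid-period).
#' @export
measurement_period <- function(start = "2018-01-01", end = "2018-12-31") {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("invalid measurement period: need start <= end")
  }
  structure(
    list(start = start, end = end,
         mid = start + floor(as.integer(end - start) / 2)),
    class = "fqm_period"
  )
}

#' @export
print.fqm_period <- function(x, ...) {
  cat(sprintf("Measurement period: %s to %s\n", x$start, x$end))
  invisible(x)
}

stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be a probability in [0, 1]", what))
  }
  invisible(x)
}

stopifnot_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("%s must be a positive integer", what))
  }
  invisible(x)
}
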