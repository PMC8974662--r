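# Internal time scale: numeric days since 1970-01-01, fractional days allowed.
# One year = 365.25 days; one month of age = 365.25/12 days.

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 365.25 / 12

#' Convert dates to internal day numbers
#'
#' The package represents time as numeric days since 1970-01-01, with
#' fractional days allowed so that simulated event times are continuous.
#' `as_days()` accepts `Date`, ISO-8601 strings, or numerics (passed
#' through); `as_date()` converts day numbers back to `Date`, truncating
#' fractional days.
#'
#' @param x A `Date`, character (ISO-8601), or numeric vector.
#' @return Numeric vector of days since 1970-01-01.
#' @examples
#' as_days("2010-01-15")
#' as_date(14624)
#' @export
as_days <- function(x) {
  if (inherits(x, "Date")) return(as.numeric(x))
  if (is.character(x)) return(as.numeric(as.Date(x)))
  if (is.numeric(x)) return(as.numeric(x))
  abort("`x` must be a Date, ISO-8601 string, or numeric days.")
}

#' @rdname as_days
#' @export
as_date <- function(x) as.Date(floor(as_days(x)), origin = "1970-01-01")

#' Age grid for under-5 mortality estimation
#'
#' Returns the age-segment boundaries, in exact days, used to disaggregate
#' events and exposure: a neonatal segment of 0--28 days followed by
#' completed-month segments ending at 3, 5, 12, 24, 36, 48, and 60 months
#' (one month = 365.25/12 days). Segments are half-open `[lo, hi)`: an
#' event at an exact boundary age belongs to the higher segment.
#'
#' @param first_cut Days at which the first segment ends. Defaults to 28
#'   (the neonatal definition); set `first_cut = DAYS_PER_MONTH` to use a
#'   1-calendar-month first segment instead.
#' @return Numeric vector of 9 strictly increasing boundaries starting at 0
#'   and ending at 60 months, with a `labels` attribute naming the 8
#'   segments.
#' @examples
#' under5_age_grid()
#' @export
under5_age_grid <- function(first_cut = 28) {
  months <- c(3, 5, 12, 24, 36, 48, 60)
  bounds <- c(0, first_cut, months * DAYS_PER_MONTH)
  stopifnot(all(diff(bounds) > 0))
  attr(bounds, "labels") <- c(
    "0-27d", "28d-2m", "3-4m", "5-11m", "12-23m", "24-35m", "36-47m", "48-59m"
  )
  bounds
}

validate_age_grid <- function(age_grid) {
  if (!is.numeric(age_grid) || length(age_grid) < 2) {
    abort("`age_grid` must be a numeric vector of at least 2 boundaries.")
  }
  if (age_grid[1] != 0) abort("`age_grid` must start at age 0.")
  if (any(diff(age_grid) <= 0)) abort("`age_grid` must be strictly increasing.")
  invisible(age_grid)
}

#' Calendar period grid
#'
#' Builds consecutive calendar windows of fixed width extending backwards
#' from an anchor date, as used for period (synthetic-cohort) estimation.
#' Windows are half-open `[start, end)`, contiguous and non-overlapping.
#'
#' @param anchor Date (or ISO string / day number) marking the end of the
#'   most recent period; typically Jan 1 following the last year of data.
#' @param width_years Window width in years (default 5; 10 supported for
#'   robustness checks).
#' @param n_periods Number of windows extending backwards from `anchor`.
#' @return A tibble with columns `period` (label, e.g. `"2010-2014"`),
#'   `start`, `end` (numeric days, half-open).
#' @examples
#' period_grid("2015-01-01", width_years = 5, n_periods = 2)
#' @export
period_grid <- function(anchor, width_years = 5, n_periods = 1) {
  stopifnot(width_years > 0, n_periods >= 1)
  anchor <- as_days(anchor)
  ends <- anchor - (seq_len(n_periods) - 1) * width_years * DAYS_PER_YEAR
  starts <- ends - width_years * DAYS_PER_YEAR
  tibble::tibble(
    period = paste0(
      format(as_date(starts), "%Y"), "-",
      format(as_date(ends - 1), "%Y")
    ),
    start = starts,
    end = ends
  ) |>
    dplyr::arrange(.data$start)
}

#' Default period anchor for an episode table
#'
#' The day after the last exit date in the data, rounded up to the next
#' January 1 (so periods align with calendar years).
#'
#' @param episodes Episode tibble with an `exit_date` column.
#' @return Numeric day number of the anchor.
#' @export
default_anchor <- function(episodes) {
  last_exit <- max(as_days(episodes$exit_date))
  yr <- as.integer(format(as_date(last_exit), "%Y"))
  as_days(paste0(yr + 1L, "-01-01"))
}

#' Time-prior-to-survey (TIPS) windows
#'
#' Retrospective reporting windows for birth-history estimation: window 0
#' covers the 0--4 years before the survey date, window 1 the 5--9 years,
#' and so on. Windows are 5 years wide, half-open, and abut at
#' `survey_date - 5 years`.
#'
#' @param survey_date Date of the survey (Date, ISO string, or day number).
#' @param n_windows Number of 5-year windows (default 2, i.e. 0--4 and
#'   5--9 years prior).
#' @return A tibble with columns `period` (`"0-4y prior"`, ...), `start`,
#'   `end` (numeric days).
#' @examples
#' tips_windows("2015-06-01")
#' @export
tips_windows <- function(survey_date, n_windows = 2) {
  stopifnot(n_windows >= 1)
  survey_date <- as_days(survey_date)
  idx <- seq_len(n_windows) - 1
  tibble::tibble(
    period = paste0(5 * idx, "-", 5 * idx + 4, "y prior"),
    start = survey_date - (idx + 1) * 5 * DAYS_PER_YEAR,
    end = survey_date - idx * 5 * DAYS_PER_YEAR
  ) |>
    dplyr::arrange(.data$start)
}
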