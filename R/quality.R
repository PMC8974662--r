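#' Expected day-of-month distribution of deaths
#'
#' The frequency of each calendar day 1--31 across a (non-leap) year:
#' 12/365 for days 1--28, 11/365 for days 29 and 30, and 7/365 for day
#' 31. Used as the reference distribution for day-of-death digit
#' preference; the fixed 365-day denominator is used even for leap-year
#' data.
#'
#' @return Numeric vector of 31 proportions summing to 1.
#' @export
expected_day_distribution <- function() {
  c(rep(12, 28), 11, 11, 7) / 365
}

#' Index of Dissimilarity for day-of-death digit preference
#'
#' Compares the observed distribution of the calendar day of month of
#' reported deaths (days 1--31) with the expected distribution from
#' [expected_day_distribution()]: half the summed absolute deviation
#' between the two. 0 means no digit preference; values near 1 mean
#' extreme concentration on rarely-expected days.
#'
#' @param death_dates Dates of death (Date/ISO/day numbers), or
#'   alternatively integer days of month 1--31 via `days_of_month`.
#' @param days_of_month Optional integer vector of day-of-month values,
#'   bypassing date parsing.
#' @return A list of class `digit_preference` with elements `index`,
#'   `observed`, `expected` (31 proportions each), and `n`.
#' @examples
#' digit_preference_id(days_of_month = rep(1:31, 5))$index
#' @export
digit_preference_id <- function(death_dates = NULL, days_of_month = NULL) {
  if (is.null(days_of_month)) {
    if (is.null(death_dates) || length(death_dates) == 0) {
      abort("At least one death date is required.")
    }
    days_of_month <- as.integer(format(as_date(death_dates), "%d"))
  }
  if (length(days_of_month) == 0) abort("At least one death date is required.")
  if (any(days_of_month < 1 | days_of_month > 31)) {
    abort("Days of month must lie in 1..31.")
  }
  observed <- tabulate(days_of_month, nbins = 31) / length(days_of_month)
  expected <- expected_day_distribution()
  structure(
    list(index = sum(abs(observed - expected)) / 2,
         observed = observed, expected = expected,
         n = length(days_of_month)),
    class = "digit_preference"
  )
}

#' @export
print.digit_preference <- function(x, ...) {
  cat("<digit_preference> index =", signif(x$index, 5), "on", x$n, "deaths\n")
  invisible(x)
}

#' Birth-history data-quality composite
#'
#' A simplified data-quality score for full-birth-history data, combining
#' three sub-indices per region:
#' \itemize{
#'   \item incompleteness: share of records missing the day or month of
#'     birth (columns `dob_day_missing` / `dob_month_missing`, taken as
#'     all-present when absent);
#'   \item age-at-death heaping: deaths reported at 12 months divided by
#'     the mean of deaths at 10, 11, 13, and 14 months (month at death =
#'     nearest whole month of 365.25/12 days; 1 when numerator and
#'     neighbors are both zero; undefined when neighbors are zero but the
#'     numerator is not);
#'   \item boundary displacement: births reported in the year just before
#'     the 5-year pre-survey boundary divided by births in the year just
#'     after it.
#' }
#' The composite is the mean of the z-scores of the three sub-indices
#' across the input regions (oriented so larger = worse quality), and is
#' 0 for a single region.
#'
#' @param records Birth-history tibble (see [estimate_fbh()]) with a
#'   `region` column.
#' @param tips_boundary Boundary date (default: survey date minus 5
#'   years).
#' @return Tibble with one row per region: `incompleteness`,
#'   `heaping_index`, `displacement_ratio`, `composite`.
#' @export
fbh_quality <- function(records, tips_boundary = NULL) {
  svy <- as_days(records$survey_date[1])
  if (is.null(tips_boundary)) tips_boundary <- svy - 5 * DAYS_PER_YEAR
  tips_boundary <- as_days(tips_boundary)
  if (!"region" %in% names(records)) records$region <- "all"
  day_missing <- records[["dob_day_missing"]] %||% rep(FALSE, nrow(records))
  month_missing <- records[["dob_month_missing"]] %||% rep(FALSE, nrow(records))
  records$._incomplete <- day_missing | month_missing

  one_region <- function(df, key) {
    months_at_death <- round(df$age_at_death_days[!df$survived] / DAYS_PER_MONTH)
    d12 <- sum(months_at_death == 12, na.rm = TRUE)
    neigh <- mean(c(sum(months_at_death == 10, na.rm = TRUE),
                    sum(months_at_death == 11, na.rm = TRUE),
                    sum(months_at_death == 13, na.rm = TRUE),
                    sum(months_at_death == 14, na.rm = TRUE)))
    heaping <- if (neigh == 0 && d12 == 0) {
      1
    } else if (neigh == 0) {
      NA_real_
    } else {
      d12 / neigh
    }
    dob <- as_days(df$dob_reported)
    before <- sum(dob >= tips_boundary - DAYS_PER_YEAR & dob < tips_boundary)
    after <- sum(dob >= tips_boundary & dob < tips_boundary + DAYS_PER_YEAR)
    tibble::tibble(
      n = nrow(df),
      incompleteness = mean(df$._incomplete),
      heaping_index = heaping,
      displacement_ratio = if (after == 0) NA_real_ else before / after
    )
  }

  out <- records |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(one_region) |>
    dplyr::ungroup()
  if (any(is.na(out$heaping_index))) {
    warn("Heaping index undefined for some region(s): deaths at 12 months with no neighboring-month deaths.")
  }
  zscore <- function(x) {
    if (length(x) < 2 || sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      rep(0, length(x))
    } else {
      (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
    }
  }
  dplyr::mutate(
    out,
    composite = rowMeans(cbind(zscore(.data$incompleteness),
                               zscore(.data$heaping_index),
                               zscore(.data$displacement_ratio)),
                         na.rm = TRUE)
  )
}
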