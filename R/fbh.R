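#' Under-5 mortality estimation from full birth histories
#'
#' The retrospective (FBH) estimator: assigns each reported child's
#' births, deaths, and exposure time to age segments within 5-year
#' windows 0--4 and 5--9 years prior to the survey, then reuses the same
#' rate and cumulative-hazard machinery as the surveillance estimator
#' ([split_exposure()], [exposure_rates()], [cumulate_probabilities()]).
#'
#' Each child contributes exposure from birth (or the window start, if
#' born earlier --- left truncation at the then-current age) to death, the
#' window end, or the survey date, whichever comes first. Sampling
#' weights, when present, multiply both deaths and person-years, so
#' constant weights leave the rates unchanged.
#'
#' @param records Birth-history tibble: `dob_reported`, `survived`
#'   (logical), `age_at_death_days` (`NA` for survivors), `survey_date`,
#'   optionally `region`, `residence`, and `weight` (default 1).
#' @param n_windows Number of 5-year pre-survey windows (default 2:
#'   0--4 and 5--9 years prior).
#' @param windows Period tibble overriding `n_windows` (e.g. a 10-year
#'   window for robustness checks).
#' @param age_grid Age boundaries in days.
#' @param aggregation `"subnational"` (by `region`, default),
#'   `"national"` (pooled), or `"residence"` (by a `residence` column).
#' @param source_label Label stamped on the output `source` column
#'   (default `"FBH"`).
#' @param low_exposure_threshold Passed to [cumulate_probabilities()].
#' @return Tibble of probability sets, one row per window x stratum, same
#'   columns as [estimate_hdss()].
#' @examples
#' cfg <- sim_config(seed = 3, annual_births = 500)
#' pop <- simulate_population(cfg)
#' fbh <- simulate_fbh_survey(pop, cfg)
#' estimate_fbh(fbh)
#' @export
estimate_fbh <- function(records, n_windows = 2, windows = NULL,
                         age_grid = under5_age_grid(),
                         aggregation = c("subnational", "national", "residence"),
                         source_label = "FBH",
                         low_exposure_threshold = 50) {
  aggregation <- match.arg(aggregation)
  if (!"survey_date" %in% names(records)) abort("`records` must carry `survey_date`.")
  svy <- as_days(records$survey_date)
  if (length(unique(svy)) > 1) {
    abort("All records must share one survey date; estimate surveys separately.")
  }
  svy1 <- svy[1]
  if (is.null(windows)) windows <- tips_windows(svy1, n_windows)

  dob <- as_days(records$dob_reported)
  if (any(dob > svy)) abort("Reported birth date after the survey date.")
  dead <- !records$survived
  age_d <- records$age_at_death_days
  if (any(dead & is.na(age_d))) abort("Dead children must carry an age at death.")
  if (any(dead & dob + age_d > svy, na.rm = TRUE)) {
    abort("Reported age at death implies death after the survey date.")
  }

  episodes <- tibble::tibble(
    dob = dob,
    entry_date = dob,
    exit_date = ifelse(dead, dob + age_d, svy),
    exit_type = ifelse(dead, "death", "censor"),
    weight = if ("weight" %in% names(records)) records$weight else 1
  )
  by <- switch(aggregation,
    subnational = "region",
    national = character(0),
    residence = "residence"
  )
  if (length(by) == 1) {
    if (!by %in% names(records)) {
      abort(paste0("Aggregation '", aggregation, "' needs a `", by, "` column."))
    }
    episodes[[by]] <- records[[by]]
  }

  split_fun <- function(df) {
    split_exposure(df, age_grid, windows, exposure_start = "entry") |>
      exposure_rates()
  }
  rates <- if (length(by) == 0) {
    split_fun(episodes)
  } else {
    episodes |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(function(df, key) split_fun(df)) |>
      dplyr::ungroup()
  }
  cumulate_probabilities(rates, low_exposure_threshold) |>
    dplyr::mutate(source = source_label)
}

#' Decode survey-style ages at death to exact days
#'
#' Survey recodes often store age at death as a coded unit/value pair
#' (days, months, or years). This shim maps such codes to exact days for
#' use in [estimate_fbh()]: days are taken as-is, while ages in completed
#' months or years are mapped to the interval midpoint (`(m + 0.5)` months
#' of 365.25/12 days; `(y + 0.5)` years of 365.25 days).
#'
#' @param value Integer age value.
#' @param unit Character vector: `"days"`, `"months"`, or `"years"`.
#' @return Numeric age at death in days.
#' @examples
#' decode_age_at_death(c(5, 3, 1), c("days", "months", "years"))
#' @export
decode_age_at_death <- function(value, unit) {
  unit <- match.arg(unit, c("days", "months", "years"), several.ok = TRUE)
  if (length(unit) == 1) unit <- rep(unit, length(value))
  dplyr::case_when(
    unit == "days" ~ as.numeric(value),
    unit == "months" ~ (value + 0.5) * DAYS_PER_MONTH,
    unit == "years" ~ (value + 0.5) * DAYS_PER_YEAR
  )
}
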