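#' Split residency episodes into age-segment x period cells
#'
#' Partitions each episode's observed lifetime simultaneously by exact age
#' and calendar time (Lexis splitting), accumulating person-years and
#' death counts into every age-segment x calendar-period cell it crosses.
#' Intervals are half-open in both dimensions: `[lo, hi)` ages and
#' `[start, end)` periods, so a death at an exact boundary belongs to the
#' higher segment/later period.
#'
#' Exposure runs from the entry date (or the surveillance observation date
#' under `exposure_start = "observation"`, the left-truncation sensitivity
#' analysis) to the exit date, restricted to ages below the last age-grid
#' boundary and to the period span. A death exit increments the cell
#' containing the exact death age and date; deaths at ages at or beyond
#' the last boundary are excluded from the cells (a note reports how
#' many). Under the observation-date rule, episodes lacking an observation
#' date are excluded (noted), and deaths occurring before the observation
#' date are not counted.
#'
#' @param episodes Tibble with columns `dob`, `entry_date`, `exit_date`,
#'   `exit_type` (`"death"` or other), optionally `obs_date` and `weight`
#'   (default 1). Dates as Date/ISO/day numbers.
#' @param age_grid Age boundaries in days, from [under5_age_grid()].
#' @param periods Period tibble from [period_grid()] or [tips_windows()].
#' @param exposure_start `"entry"` (default) or `"observation"`.
#' @return A tibble with one row per age segment x period:
#'   `age_segment`, `age_lo`, `age_hi` (days), `period`, `period_start`,
#'   `period_end`, `deaths`, `person_years`.
#' @examples
#' eps <- tibble::tibble(
#'   dob = 0, entry_date = 0, exit_date = 45, exit_type = "death"
#' )
#' split_exposure(eps, under5_age_grid(), period_grid(3650, n_periods = 1))
#' @export
split_exposure <- function(episodes, age_grid = under5_age_grid(),
                           periods, exposure_start = c("entry", "observation")) {
  exposure_start <- match.arg(exposure_start)
  validate_age_grid(age_grid)
  stopifnot(all(c("start", "end", "period") %in% names(periods)))

  dob <- as_days(episodes$dob)
  entry <- as_days(episodes$entry_date)
  exit <- as_days(episodes$exit_date)
  if (any(exit < entry)) abort("Episode exit before entry.")
  w <- if ("weight" %in% names(episodes)) episodes$weight else rep(1, nrow(episodes))
  if (any(w < 0)) abort("Negative weights are not allowed.")

  if (exposure_start == "observation") {
    if (!"obs_date" %in% names(episodes)) {
      abort("`exposure_start = \"observation\"` requires an `obs_date` column.")
    }
    obs <- as_days(episodes$obs_date)
    missing_obs <- is.na(obs)
    if (any(missing_obs)) {
      inform(paste0(sum(missing_obs),
                    " episode(s) without an observation date excluded under the observation-date rule."))
    }
    keep <- !missing_obs
    dob <- dob[keep]; entry <- obs[keep]; exit <- exit[keep]; w <- w[keep]
    is_death <- episodes$exit_type[keep] == "death"
  } else {
    is_death <- episodes$exit_type == "death"
  }

  labels <- attr(age_grid, "labels") %||% paste0("seg", seq_len(length(age_grid) - 1))
  n_seg <- length(age_grid) - 1
  n_per <- nrow(periods)
  max_age <- age_grid[length(age_grid)]

  death_age <- exit - dob
  over_age_deaths <- sum(is_death & death_age >= max_age &
                           exit >= entry, na.rm = TRUE)
  if (over_age_deaths > 0) {
    inform(paste0(over_age_deaths,
                  " death(s) at or beyond the last age boundary excluded from the cells."))
  }

  out <- vector("list", n_seg * n_per)
  k <- 0
  for (p in seq_len(n_per)) {
    ps <- periods$start[p]; pe <- periods$end[p]
    for (j in seq_len(n_seg)) {
      lo <- age_grid[j]; hi <- age_grid[j + 1]
      overlap <- pmax(0, pmin(exit, dob + hi, pe) - pmax(entry, dob + lo, ps))
      d <- is_death & death_age >= lo & death_age < hi &
        exit >= ps & exit < pe & exit >= entry
      k <- k + 1
      out[[k]] <- tibble::tibble(
        age_segment = labels[j], age_lo = lo, age_hi = hi,
        period = periods$period[p],
        period_start = ps, period_end = pe,
        deaths = sum(w * d),
        person_years = sum(w * overlap) / DAYS_PER_YEAR
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Mortality rates from age-period cells
#'
#' The standard demographic calculation of observed deaths over
#' person-years, per cell. Cells with zero exposure are flagged undefined
#' rather than imputed (silent zeros would bias probabilities downward).
#'
#' @param cells Tibble from [split_exposure()].
#' @return `cells` with added columns `rate` (deaths per person-year; `NA`
#'   where undefined) and `undefined` (logical).
#' @export
exposure_rates <- function(cells) {
  dplyr::mutate(
    cells,
    undefined = .data$person_years == 0,
    rate = dplyr::if_else(.data$person_years > 0,
                          .data$deaths / .data$person_years, NA_real_)
  )
}

#' Aggregate piecewise-constant rates into under-5 probabilities
#'
#' For each period (and any extra grouping columns), aggregates the
#' per-segment rates into cumulative hazards over the nested age ranges
#' 0--28d, 28d--12m, 0--12m, 12m--5y, and 0--5y, and converts them to
#' probabilities of dying: `q = 1 - exp(-sum(m * width_years))`. The
#' composition identities `q12m = 1-(1-q28d)(1-qpnn)` and
#' `q5y = 1-(1-q12m)(1-qchild)` hold exactly by construction.
#'
#' A cell with deaths but zero exposure is an error naming the offending
#' cell; a cell with neither deaths nor exposure contributes zero hazard
#' and is surfaced through the small-exposure flag. Periods where any
#' segment has fewer than `low_exposure_threshold` person-years are
#' flagged, with a warning, as resting on small exposure.
#'
#' @param rates Tibble from [exposure_rates()]; may carry extra grouping
#'   columns (e.g. `region`) alongside `period`.
#' @param low_exposure_threshold Person-years below which a segment
#'   triggers the small-exposure flag (default 50).
#' @return A tibble with one row per period (x extra groups): `q28d`,
#'   `qpnn`, `q12m`, `qchild`, `q5y`, `deaths`, `person_years`,
#'   `low_exposure`.
#' @export
cumulate_probabilities <- function(rates, low_exposure_threshold = 50) {
  group_cols <- intersect(c("region", "subregion", "residence", "stratum",
                            "source", "period"),
                          names(rates))
  if (!"period" %in% group_cols) abort("`rates` must carry a `period` column.")

  y1 <- 12 * DAYS_PER_MONTH
  one_group <- function(df, key) {
    bad <- df$undefined & df$deaths > 0
    if (any(bad)) {
      abort(paste0(
        "Undefined rate (zero exposure) in segment ", df$age_segment[bad][1],
        ", period ", key$period[1],
        ": deaths observed with no exposure in the target age range."
      ))
    }
    # segments with neither exposure nor deaths contribute zero hazard;
    # they are surfaced through the low-exposure flag rather than an error
    df$rate[df$undefined] <- 0
    bounds <- sort(unique(c(df$age_lo, df$age_hi)))
    first_cut <- bounds[2]
    y5 <- 60 * DAYS_PER_MONTH
    if (!all(c(y1, y5) %in% bounds)) {
      abort("Age grid must include boundaries at 12 and 60 months.")
    }
    width_years <- (df$age_hi - df$age_lo) / DAYS_PER_YEAR
    H <- function(a, b) sum((df$rate * width_years)[df$age_lo >= a & df$age_hi <= b])
    q <- function(a, b) 1 - exp(-H(a, b))
    q28d <- q(0, first_cut)
    qpnn <- q(first_cut, y1)
    qchild <- q(y1, y5)
    tibble::tibble(
      q28d = q28d,
      qpnn = qpnn,
      q12m = 1 - (1 - q28d) * (1 - qpnn),
      qchild = qchild,
      q5y = 1 - (1 - q28d) * (1 - qpnn) * (1 - qchild),
      deaths = sum(df$deaths),
      person_years = sum(df$person_years),
      low_exposure = any(df$person_years < low_exposure_threshold)
    )
  }

  out <- rates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(one_group) |>
    dplyr::ungroup()
  if (any(out$low_exposure)) {
    warn(paste0(sum(out$low_exposure),
                " period estimate(s) rest on segments with < ",
                low_exposure_threshold, " person-years."))
  }
  out
}

#' Direct under-5 mortality estimation from surveillance episodes
#'
#' The surveillance (HDSS) estimator: splits episodes into age x period
#' cells, computes piecewise-constant rates, and aggregates them into the
#' five under-5 probabilities of dying, one probability set per period and
#' stratum.
#'
#' @param episodes Episode tibble (see [split_exposure()]); stratum
#'   columns among `region`, `subregion` are used for grouping.
#' @param periods Period tibble from [period_grid()]; default: 5-year
#'   periods extending backwards from [default_anchor()] covering the data.
#' @param age_grid Age boundaries in days.
#' @param exposure_start `"entry"` (default) or `"observation"` (exposure
#'   counted from the surveillance observation date; left-truncation
#'   sensitivity analysis).
#' @param by Character vector of stratum columns to estimate within
#'   (default `"region"`; use `c("region","subregion")` or `NULL` for a
#'   single pooled stratum).
#' @param width_years,n_periods Used to build the default period grid.
#' @param low_exposure_threshold Passed to [cumulate_probabilities()].
#' @return Tibble of probability sets: stratum columns, `period`, `q28d`,
#'   `qpnn`, `q12m`, `qchild`, `q5y`, `deaths`, `person_years`,
#'   `low_exposure`, `source = "HDSS"`.
#' @examples
#' pop <- simulate_population(sim_config(seed = 7, annual_births = 500))
#' estimate_hdss(pop$episodes, n_periods = 2)
#' @export
estimate_hdss <- function(episodes, periods = NULL,
                          age_grid = under5_age_grid(),
                          exposure_start = c("entry", "observation"),
                          by = "region",
                          width_years = 5, n_periods = 2,
                          low_exposure_threshold = 50) {
  exposure_start <- match.arg(exposure_start)
  if (is.null(periods)) {
    periods <- period_grid(default_anchor(episodes), width_years, n_periods)
  }
  by <- intersect(by, names(episodes))
  split_fun <- function(df) {
    split_exposure(df, age_grid, periods, exposure_start) |>
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
    dplyr::mutate(source = "HDSS")
}
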