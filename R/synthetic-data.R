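#' Configuration for the surveillance microsimulation
#'
#' Bundles all parameters of the synthetic population generator: the
#' calendar span and birth stream, the true mortality hazard, migration,
#' the surveillance interview calendar and ascertainment of left-censored
#' deaths, and the birth-history reporting-error processes (omission of
#' dead children, backward displacement of birth dates across the 5-year
#' health-data boundary, and heaping of ages at death on 1 and 12 months).
#'
#' All error processes default to off, so the default configuration
#' produces faithfully reported data with known true mortality.
#'
#' @param seed Integer seed; the same seed and configuration reproduce
#'   byte-identical output.
#' @param start,end Calendar span (Date/ISO/day number). Must cover at
#'   least one full 5-year period.
#' @param annual_births Expected live births per calendar year.
#' @param hazard A [hazard_schedule()] giving the true age-specific
#'   mortality rates.
#' @param out_migration_rate Constant out-migration hazard, per person-year.
#' @param in_migration_rate Expected in-migrating under-5 children per year
#'   (Poisson stream; ages at entry uniform over 0--59 months).
#' @param interview_interval_months Months between surveillance rounds;
#'   rounds fall on the 1st of the month.
#' @param round_start First interview round (default: Jan 1 of the start
#'   year).
#' @param ascertainment Probability that an individual dying before their
#'   first surveillance observation is nevertheless recorded (1 = no
#'   under-ascertainment of left-censored deaths).
#' @param omission_prob Named probabilities (`neonatal`, `postneonatal`,
#'   `child`) that a dead child is omitted from the birth history,
#'   by age-at-death class (< 28 days, 28 days--1 year, 1--5 years), or a
#'   single probability applied to all classes.
#' @param displacement_prob Probability that a child truly born in the
#'   0--4-year pre-survey window has their birth date displaced backward
#'   across the window boundary.
#' @param displacement_jitter_days Width of the uniform jitter by which a
#'   displaced birth date lands before the boundary.
#' @param heaping_prob Probability that a reported age at death near a
#'   central age is heaped onto it: deaths within 14 days of age 28 days
#'   are reported at exactly 28 days ("1 month"), deaths within 61 days
#'   of exact age 1 year at exactly 12 months. A single number applies to
#'   both targets; a named vector `c(m1 = , m12 = )` sets them
#'   separately.
#' @param mean_parity Mean children per synthetic mother (children are
#'   assigned to mothers uniformly at random).
#' @param region,subregion Stratum labels attached to all output rows.
#' @param survey_date Birth-history interview date (default: `end`). Must
#'   lie within the calendar span.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, annual_births = 200)
#' @export
sim_config <- function(seed = 1L,
                       start = "2000-01-01",
                       end = "2015-01-01",
                       annual_births = 1000,
                       hazard = default_hazard(),
                       out_migration_rate = 0.05,
                       in_migration_rate = 0,
                       interview_interval_months = 4,
                       round_start = NULL,
                       ascertainment = 1,
                       omission_prob = 0,
                       displacement_prob = 0,
                       displacement_jitter_days = 90,
                       heaping_prob = 0,
                       mean_parity = 4,
                       region = "Region A",
                       subregion = "Eastern",
                       survey_date = NULL) {
  start <- as_days(start)
  end <- as_days(end)
  if (end <= start) abort("Calendar span is empty: `end` must be after `start`.")
  if (end - start < 5 * 365) {
    abort("Calendar span must cover at least one full 5-year period.")
  }
  if (!inherits(hazard, "hazard_schedule")) abort("`hazard` must be a hazard_schedule.")
  if (interview_interval_months <= 0) abort("`interview_interval_months` must be > 0.")
  if (length(omission_prob) == 1 && is.null(names(omission_prob))) {
    omission_prob <- c(neonatal = omission_prob, postneonatal = omission_prob,
                       child = omission_prob)
  }
  req <- c("neonatal", "postneonatal", "child")
  if (!all(req %in% names(omission_prob))) {
    abort("`omission_prob` must be a single number or named for neonatal/postneonatal/child.")
  }
  omission_prob <- omission_prob[req]
  if (length(heaping_prob) == 1 && is.null(names(heaping_prob))) {
    heaping_prob <- c(m1 = unname(heaping_prob), m12 = unname(heaping_prob))
  }
  if (!all(c("m1", "m12") %in% names(heaping_prob))) {
    abort("`heaping_prob` must be a single number or named c(m1 = , m12 = ).")
  }
  heaping_prob <- heaping_prob[c("m1", "m12")]
  probs <- c(ascertainment, omission_prob, displacement_prob, heaping_prob)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (is.null(survey_date)) survey_date <- end
  survey_date <- as_days(survey_date)
  if (survey_date < start || survey_date > end) {
    abort("`survey_date` must lie within the calendar span.")
  }
  if (is.null(round_start)) {
    round_start <- as_days(paste0(format(as_date(start), "%Y"), "-01-01"))
  }
  structure(
    list(
      seed = as.integer(seed), start = start, end = end,
      annual_births = annual_births, hazard = hazard,
      out_migration_rate = out_migration_rate,
      in_migration_rate = in_migration_rate,
      interview_interval_months = interview_interval_months,
      round_start = as_days(round_start),
      ascertainment = ascertainment,
      omission_prob = omission_prob,
      displacement_prob = displacement_prob,
      displacement_jitter_days = displacement_jitter_days,
      heaping_prob = heaping_prob,
      mean_parity = mean_parity,
      region = region, subregion = subregion,
      survey_date = survey_date
    ),
    class = "sim_config"
  )
}

#' Simulate a surveillance population
#'
#' Draws a birth cohort (uniform birth stream over the calendar span),
#' assigns death ages from the piecewise-exponential law of the configured
#' hazard schedule, adds constant-hazard out-migration and a Poisson
#' in-migration stream of under-5 children, and emits one residency
#' episode per uninterrupted spell. Also returns the latent child fates
#' (used by the birth-history simulator) and the population truth: the
#' closed-form probability set of the generating hazards plus realized
#' birth and death counts by age segment.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_population` with elements
#'   `episodes` (tibble: `id`, `mother_id`, `dob`, `entry_date`,
#'   `entry_type`, `exit_date`, `exit_type`, `obs_date`, `region`,
#'   `subregion`), `children` (latent fates of locally-born children:
#'   `death_age_days` is `Inf` for survivors), and `truth` (list:
#'   `prob` one-row tibble of the five true q's, `hazard`, `births`,
#'   `deaths_by_segment`).
#' @examples
#' pop <- simulate_population(sim_config(seed = 42, annual_births = 100))
#' nrow(pop$episodes)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  span_years <- (config$end - config$start) / DAYS_PER_YEAR
  n_births <- round(config$annual_births * span_years)
  age60 <- 60 * DAYS_PER_MONTH

  dob <- sort(config$start + runif(n_births) * (config$end - config$start))
  n_mothers <- max(1L, round(n_births / config$mean_parity))
  mother_id <- sample.int(n_mothers, n_births, replace = TRUE)
  death_age <- sample_death_age(n_births, config$hazard)
  outmig_age <- if (config$out_migration_rate > 0) {
    rexp(n_births, config$out_migration_rate) * DAYS_PER_YEAR
  } else {
    rep(Inf, n_births)
  }

  born <- tibble::tibble(
    id = paste0("B", seq_len(n_births)),
    mother_id = paste0("M", mother_id),
    dob = dob,
    entry_date = dob,
    entry_type = "birth",
    death_date = dob + death_age,
    outmig_date = dob + outmig_age
  )

  # in-migration: Poisson stream of under-5 children at uniform entry ages,
  # mortality applied conditionally on survival to the age at entry
  n_in <- if (config$in_migration_rate > 0) rpois(1, config$in_migration_rate * span_years) else 0L
  inmig <- NULL
  if (n_in > 0) {
    entry <- config$start + runif(n_in) * (config$end - config$start)
    entry_age <- runif(n_in, 0, age60)
    d_age <- sample_death_age(n_in, config$hazard, entry_age_days = entry_age)
    o_age <- if (config$out_migration_rate > 0) {
      entry_age + rexp(n_in, config$out_migration_rate) * DAYS_PER_YEAR
    } else {
      rep(Inf, n_in)
    }
    inmig <- tibble::tibble(
      id = paste0("I", seq_len(n_in)),
      mother_id = NA_character_,
      dob = entry - entry_age,
      entry_date = entry,
      entry_type = "in-migration",
      death_date = entry - entry_age + d_age,
      outmig_date = entry - entry_age + o_age
    )
  }

  all_ind <- dplyr::bind_rows(born, inmig)
  exit_date <- pmin(all_ind$death_date, all_ind$outmig_date, config$end)
  exit_type <- dplyr::case_when(
    all_ind$death_date <= pmin(all_ind$outmig_date, config$end) ~ "death",
    all_ind$outmig_date <= config$end ~ "out-migration",
    .default = "censor"
  )

  episodes <- tibble::tibble(
    id = all_ind$id,
    mother_id = all_ind$mother_id,
    dob = all_ind$dob,
    entry_date = all_ind$entry_date,
    entry_type = all_ind$entry_type,
    exit_date = exit_date,
    exit_type = exit_type,
    obs_date = NA_real_,
    region = config$region,
    subregion = config$subregion
  )

  children <- tibble::tibble(
    id = born$id,
    mother_id = born$mother_id,
    dob = born$dob,
    death_age_days = death_age,
    region = config$region
  )

  bounds <- config$hazard$boundaries
  seg <- findInterval(death_age[is.finite(death_age)], bounds,
                      rightmost.closed = FALSE)
  seg <- seg[seg <= length(bounds) - 1]
  deaths_by_segment <- tibble::tibble(
    age_lo = bounds[-length(bounds)],
    age_hi = bounds[-1],
    deaths = as.integer(tabulate(seg, nbins = length(bounds) - 1))
  )

  structure(
    list(
      episodes = episodes,
      children = children,
      truth = list(
        prob = true_probability_set(config$hazard),
        hazard = config$hazard,
        births = n_births,
        deaths_by_segment = deaths_by_segment
      )
    ),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population>", nrow(x$episodes), "episodes,",
      x$truth$births, "births; true q(5y) =",
      signif(x$truth$prob$q5y, 4), "\n")
  invisible(x)
}

# interview round dates covering [start, end], on the 1st of the month
interview_rounds <- function(config) {
  first <- as_date(config$round_start)
  by <- paste(config$interview_interval_months, "months")
  n_rounds <- ceiling((config$end - config$start) / DAYS_PER_YEAR * 12 /
                        config$interview_interval_months) + 3
  as.numeric(seq(first, by = by, length.out = n_rounds))
}

#' Apply surveillance observation to simulated episodes
#'
#' Sets each episode's observation date to the first interview round on or
#' after entry, and models under-ascertainment of left-censored vital
#' events: individuals who die before their first surveillance observation
#' are dropped with probability `1 - ascertainment`, emulating deaths that
#' occur before the household is ever enumerated and are never reported.
#'
#' @param episodes Episode tibble from [simulate_population()] (or the
#'   `sim_population` object itself).
#' @param config The [sim_config()] used to generate the episodes.
#' @return Episode tibble with `obs_date` filled in and unascertained
#'   deaths removed.
#' @export
apply_surveillance <- function(episodes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(episodes, "sim_population")) episodes <- episodes$episodes
  rounds <- interview_rounds(config)
  pos <- findInterval(episodes$entry_date, rounds)
  at_round <- pos >= 1 & rounds[pmax(pos, 1)] == episodes$entry_date
  obs_idx <- ifelse(at_round, pos, pos + 1)
  if (any(obs_idx > length(rounds))) abort("Interview round calendar does not cover all entries.")
  out <- dplyr::mutate(episodes, obs_date = rounds[obs_idx])
  withr::with_seed(config$seed + 1L, {
    pre_obs_death <- out$exit_type == "death" & out$exit_date < out$obs_date
    keep <- !pre_obs_death | runif(nrow(out)) < config$ascertainment
    out[keep, , drop = FALSE]
  })
}

#' Simulate a full-birth-history survey
#'
#' Interviews the synthetic mothers at the survey date and transcribes
#' each locally-born child into a birth-history record, then applies the
#' configured retrospective reporting errors: omission of dead children
#' (by age-at-death class), backward displacement of birth dates across
#' the 5-year pre-survey boundary, and heaping of ages at death onto 28
#' and 365 days. With all error probabilities zero the records are exact
#' transcriptions of the simulated fates.
#'
#' @param population A `sim_population` from [simulate_population()].
#' @param config The [sim_config()] (its `survey_date`, error
#'   probabilities, and labels are used).
#' @return A tibble of birth-history records: `mother_id`, `child_id`,
#'   `dob_reported`, `survived` (logical), `age_at_death_days` (`NA` for
#'   survivors), `survey_date`, `region`, `weight`.
#' @export
simulate_fbh_survey <- function(population, config) {
  stopifnot(inherits(config, "sim_config"))
  children <- if (inherits(population, "sim_population")) population$children else population
  svy <- config$survey_date
  if (svy < config$start || svy > config$end) abort("Survey date outside calendar span.")
  kids <- dplyr::filter(children, .data$dob < svy)
  death_date <- kids$dob + kids$death_age_days
  dead <- is.finite(kids$death_age_days) & death_date <= svy

  withr::with_seed(config$seed + 2L, {
    age_d <- kids$death_age_days
    class <- dplyr::case_when(
      age_d < 28 ~ "neonatal",
      age_d < 12 * DAYS_PER_MONTH ~ "postneonatal",
      .default = "child"
    )
    omit_p <- unname(config$omission_prob[class])
    omit <- dead & runif(nrow(kids)) < omit_p
    kids <- kids[!omit, , drop = FALSE]
    dead <- dead[!omit]
    age_d <- age_d[!omit]

    # displacement out of the 0-4y health-data window: birth date moved
    # backward to just before the boundary (age at death is preserved)
    boundary <- svy - 5 * DAYS_PER_YEAR
    dob_rep <- kids$dob
    in_window <- dob_rep >= boundary
    displace <- in_window & runif(nrow(kids)) < config$displacement_prob
    n_disp <- sum(displace)
    if (n_disp > 0) {
      dob_rep[displace] <- boundary - runif(n_disp, 0, config$displacement_jitter_days) -
        1e-9
    }

    # age-at-death heaping on the central ages 1 month (28 days) and 12
    # months (365.25/12 * 12 days, i.e. exactly one year of age, so an
    # upward-rounded death crosses the infancy boundary)
    age_rep <- ifelse(dead, age_d, NA_real_)
    u_heap <- runif(nrow(kids))
    m12 <- 12 * DAYS_PER_MONTH
    near28 <- dead & u_heap < config$heaping_prob[["m1"]] &
      abs(age_rep - 28) <= 14 & age_rep != 28
    near12m <- dead & u_heap < config$heaping_prob[["m12"]] & !near28 &
      abs(age_rep - m12) <= 61 & age_rep != m12
    age_rep[near28] <- 28
    age_rep[near12m] <- m12

    tibble::tibble(
      mother_id = kids$mother_id,
      child_id = kids$id,
      dob_reported = dob_rep,
      survived = !dead,
      age_at_death_days = age_rep,
      survey_date = svy,
      region = kids$region,
      weight = 1
    )
  })
}
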