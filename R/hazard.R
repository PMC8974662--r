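#' Piecewise-constant mortality hazard schedule
#'
#' A hazard schedule pairs ordered age boundaries (exact days, starting at
#' 0) with per-segment mortality rates in deaths per person-year. The
#' schedule defines a piecewise-exponential survival law on `[0, max age)`;
#' no mortality is applied beyond the last boundary (the simulator only
#' concerns ages under 5).
#'
#' @param boundaries Strictly increasing numeric ages in days, starting at 0.
#' @param rates Non-negative rates (deaths per person-year), one per
#'   segment, so `length(rates) == length(boundaries) - 1`.
#' @return An object of class `hazard_schedule`.
#' @examples
#' hazard_schedule(c(0, 28, 365.25), c(0.4, 0.05))
#' @export
hazard_schedule <- function(boundaries, rates) {
  if (boundaries[1] != 0) abort("Hazard boundaries must start at 0.")
  if (any(diff(boundaries) <= 0)) abort("Hazard boundaries must be strictly increasing.")
  if (length(rates) != length(boundaries) - 1) {
    abort("Need exactly one rate per age segment.")
  }
  if (any(rates < 0)) abort("Hazard rates must be non-negative.")
  structure(
    list(boundaries = as.numeric(boundaries), rates = as.numeric(rates)),
    class = "hazard_schedule"
  )
}

#' @export
print.hazard_schedule <- function(x, ...) {
  cat("<hazard_schedule>", length(x$rates), "segments over [0,",
      x$boundaries[length(x$boundaries)], "days)\n")
  invisible(x)
}

#' Default under-5 hazard schedule
#'
#' A schedule with rates typical of a high-mortality sub-Saharan African
#' setting: neonatal mortality of about 31 per 1,000 live births heavily
#' front-loaded into the first week of life (as early neonatal deaths
#' are), declining through infancy, with substantial mortality persisting
#' at ages 1-4 (under-5 mortality about 130 per 1,000). The schedule is
#' finer than the estimation age grid: it splits the neonatal period at
#' day 7, so the hazard is not constant within the 0--28-day estimation
#' segment.
#'
#' @return A [hazard_schedule()].
#' @export
default_hazard <- function() {
  grid <- under5_age_grid()
  hazard_schedule(
    c(0, 7, grid[-1]),
    c(1.20, 0.15, 0.08, 0.06, 0.045, 0.025, 0.015, 0.010, 0.008)
  )
}

# Cumulative hazard H(age) of a schedule, vectorized over age (days).
cumulative_hazard <- function(schedule, age_days) {
  b <- schedule$boundaries
  r <- schedule$rates
  k <- length(r)
  # overlap of [0, age) with each segment, in years
  H <- numeric(length(age_days))
  for (j in seq_len(k)) {
    H <- H + r[j] * pmax(0, pmin(age_days, b[j + 1]) - b[j]) / DAYS_PER_YEAR
  }
  H
}

#' Closed-form probability of dying between two exact ages
#'
#' Under the piecewise-exponential law of a [hazard_schedule()], the
#' probability of dying between exact ages `a` and `b`, conditional on
#' surviving to `a`, is `1 - exp(-(H(b) - H(a)))`.
#'
#' @param schedule A [hazard_schedule()].
#' @param a,b Exact ages in days, `a < b`.
#' @return Probability in `[0, 1]`.
#' @examples
#' closed_form_q(default_hazard(), 0, 28)
#' @export
closed_form_q <- function(schedule, a, b) {
  stopifnot(a < b)
  1 - exp(-(cumulative_hazard(schedule, b) - cumulative_hazard(schedule, a)))
}

#' True probability set implied by a hazard schedule
#'
#' The five under-5 quantities implied in closed form by a hazard
#' schedule: q(28d), q(28d,12m), q(12m), q(12m,5y), q(5y).
#'
#' @param schedule A [hazard_schedule()].
#' @return A one-row tibble with columns `q28d`, `qpnn`, `q12m`, `qchild`,
#'   `q5y`.
#' @export
true_probability_set <- function(schedule) {
  y1 <- 12 * DAYS_PER_MONTH
  y5 <- 60 * DAYS_PER_MONTH
  tibble::tibble(
    q28d = closed_form_q(schedule, 0, 28),
    qpnn = closed_form_q(schedule, 28, y1),
    q12m = closed_form_q(schedule, 0, y1),
    qchild = closed_form_q(schedule, y1, y5),
    q5y = closed_form_q(schedule, 0, y5)
  )
}

# Inverse-CDF draw of death ages (days) from the piecewise-exponential law,
# conditional on survival to entry_age_days. Returns Inf for individuals
# surviving past the last boundary.
sample_death_age <- function(n, schedule, entry_age_days = 0) {
  b <- schedule$boundaries
  r <- schedule$rates
  Hb <- c(0, cumsum(r * diff(b) / DAYS_PER_YEAR))
  target <- cumulative_hazard(schedule, entry_age_days) + rexp(n)
  age <- rep(Inf, n)
  hit <- target < Hb[length(Hb)]
  if (any(hit)) {
    # largest boundary index with Hb <= target; ties over zero-rate (flat)
    # segments resolve to the last duplicate, i.e. the segment that can
    # actually absorb the remaining hazard
    seg <- findInterval(target[hit], Hb)
    age[hit] <- b[seg] + (target[hit] - Hb[seg]) / r[seg] * DAYS_PER_YEAR
  }
  age
}
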