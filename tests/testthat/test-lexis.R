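one_period <- function(t0 = 0, t1 = 3000) {
  tibble::tibble(period = "P1", start = t0, end = t1)
}

test_that("a single infant death is partitioned exactly across segments", {
  eps <- tibble::tibble(dob = 0, entry_date = 0, exit_date = 45,
                        exit_type = "death")
  cells <- split_exposure(eps, under5_age_grid(), one_period())
  neo <- cells[cells$age_segment == "0-27d", ]
  seg2 <- cells[cells$age_segment == "28d-2m", ]
  expect_equal(neo$person_years, 28 / 365.25, tolerance = 1e-12)
  expect_equal(neo$deaths, 0)
  expect_equal(seg2$person_years, 17 / 365.25, tolerance = 1e-12)
  expect_equal(seg2$deaths, 1)
  expect_true(all(cells$person_years[!cells$age_segment %in%
                                       c("0-27d", "28d-2m")] == 0))
})

test_that("an empty episode list yields all-zero cells", {
  eps <- tibble::tibble(dob = numeric(0), entry_date = numeric(0),
                        exit_date = numeric(0), exit_type = character(0))
  cells <- split_exposure(eps, under5_age_grid(), period_grid(3650, n_periods = 2))
  expect_equal(nrow(cells), 16)
  expect_true(all(cells$deaths == 0 & cells$person_years == 0))
})

test_that("splitting matches the day-walk oracle on randomized episodes", {
  eps <- random_episodes(500, seed = 42)
  periods <- period_grid(as_days("1979-01-01"), width_years = 5, n_periods = 2)
  got <- suppressMessages(split_exposure(eps, under5_age_grid(), periods))
  want <- oracle_split(eps, under5_age_grid(), periods)
  merged <- dplyr::inner_join(got, want, by = c("age_segment", "period"),
                              suffix = c("", "_oracle"))
  expect_equal(nrow(merged), 16)
  expect_identical(merged$deaths, merged$deaths_oracle)
  expect_lt(max(abs(merged$person_years - merged$person_years_oracle)), 1e-9)
})

test_that("exposure is conserved across cells", {
  eps <- random_episodes(300, seed = 7)
  periods <- tibble::tibble(period = "all", start = -1e5, end = 1e5)
  cells <- suppressMessages(split_exposure(eps, under5_age_grid(), periods))
  eligible <- pmax(0, pmin(eps$exit_date, eps$dob + 60 * 365.25 / 12) -
                     pmax(eps$entry_date, eps$dob))
  expect_equal(sum(cells$person_years), sum(eligible) / 365.25,
               tolerance = 1e-9)
})

test_that("splitting is invariant to episode order and interior cuts", {
  eps <- random_episodes(120, seed = 3)
  periods <- period_grid(as_days("1979-01-01"), n_periods = 2)
  base <- suppressMessages(split_exposure(eps, under5_age_grid(), periods))
  shuffled <- eps[withr::with_seed(1, sample(nrow(eps))), ]
  expect_equal(suppressMessages(split_exposure(shuffled, under5_age_grid(), periods)),
               base)
  # cut each episode at an interior date into two abutting spells
  withr::with_seed(2, {
    cut <- eps$entry_date + runif(nrow(eps)) * (eps$exit_date - eps$entry_date)
  })
  first <- dplyr::mutate(eps, exit_date = cut, exit_type = "out-migration")
  second <- dplyr::mutate(eps, entry_date = cut)
  cut_cells <- suppressMessages(
    split_exposure(dplyr::bind_rows(first, second), under5_age_grid(), periods)
  )
  expect_identical(cut_cells$deaths, base$deaths)
  expect_equal(cut_cells$person_years, base$person_years, tolerance = 1e-9)
})

test_that("rates divide deaths by person-years and flag empty cells", {
  cells <- tibble::tibble(
    age_segment = c("a", "b", "c"), age_lo = c(0, 28, 91.3125),
    age_hi = c(28, 91.3125, 152.1875), period = "P1",
    period_start = 0, period_end = 100,
    deaths = c(1, 0, 3), person_years = c(10, 5, 0)
  )
  r <- exposure_rates(cells)
  expect_equal(r$rate[1:2], c(0.1, 0))
  expect_true(is.na(r$rate[3]))
  expect_identical(r$undefined, c(FALSE, FALSE, TRUE))
})

test_that("cumulating rates reproduces closed forms and fails on undefined cells", {
  periods <- one_period()
  grid <- under5_age_grid()
  zero <- tibble::tibble(
    age_segment = attr(grid, "labels"), age_lo = grid[-9], age_hi = grid[-1],
    period = "P1", period_start = 0, period_end = 3000,
    deaths = 0, person_years = 100
  )
  q0 <- cumulate_probabilities(exposure_rates(zero))
  expect_true(all(unlist(q0[c("q28d", "qpnn", "q12m", "qchild", "q5y")]) == 0))

  # uniform m = 0.1/yr over [0, 1y)
  m01 <- dplyr::mutate(zero, deaths = 0.1 * person_years * (age_lo < 365.25))
  q1 <- cumulate_probabilities(exposure_rates(m01))
  expect_equal(q1$q12m, 1 - exp(-0.1), tolerance = 1e-12)

  broken <- dplyr::mutate(zero,
                          person_years = ifelse(age_lo == 28, 0, 100),
                          deaths = ifelse(age_lo == 28, 2, 0))
  expect_error(cumulate_probabilities(exposure_rates(broken)),
               "Undefined rate.*28d")
  # zero deaths with zero exposure is tolerated and contributes no hazard
  empty_seg <- dplyr::mutate(zero, person_years = ifelse(age_lo == 28, 0, 100))
  expect_warning(ok <- cumulate_probabilities(exposure_rates(empty_seg)),
                 "person-years")
  expect_equal(ok$q5y, 0)
})

test_that("probability sets satisfy the composition identities", {
  sc <- small_faithful_scenario(seed = 202, annual_births = 600)
  est <- estimate_hdss(sc$eps, n_periods = 3)
  expect_equal(est$q12m, 1 - (1 - est$q28d) * (1 - est$qpnn), tolerance = 1e-12)
  expect_equal(est$q5y, 1 - (1 - est$q12m) * (1 - est$qchild), tolerance = 1e-12)
  expect_true(all(est$q5y >= est$q12m & est$q12m >= est$q28d))
})

test_that("q5y from random episodes equals the oracle's hazard cumulation", {
  eps <- random_episodes(200, seed = 11)
  periods <- tibble::tibble(period = "P1", start = 0, end = 4000)
  est <- suppressMessages(suppressWarnings(
    estimate_hdss(eps, periods = periods, by = NULL)
  ))
  ora <- oracle_split(eps, under5_age_grid(), periods)
  grid <- under5_age_grid()
  width <- diff(grid) / DPY
  m <- ora$deaths / ora$person_years
  q5y_oracle <- 1 - exp(-sum(m * width))
  expect_equal(est$q5y, q5y_oracle, tolerance = 1e-9)
})

test_that("observation-date exposure lowers neonatal estimates", {
  cfg <- sim_config(seed = 404, annual_births = 3000,
                    interview_interval_months = 6)
  pop <- simulate_population(cfg)
  eps <- apply_surveillance(pop, cfg)
  periods <- period_grid(default_anchor(eps), n_periods = 2)
  by_entry <- estimate_hdss(eps, periods = periods)
  by_obs <- estimate_hdss(eps, periods = periods, exposure_start = "observation")
  # deaths before first observation are excluded, trimming q(28d) downward
  expect_true(all(by_obs$q28d <= by_entry$q28d))
})

test_that("the observation rule excludes episodes without observation dates", {
  eps <- random_episodes(10, seed = 6)
  eps$obs_date <- c(eps$entry_date[1:5], rep(NA_real_, 5))
  periods <- tibble::tibble(period = "P1", start = -1e4, end = 1e4)
  expect_message(
    split_exposure(eps, under5_age_grid(), periods, "observation"),
    "without an observation date"
  )
})

test_that("small exposure triggers the low-exposure flag and warning", {
  eps <- tibble::tibble(dob = 0, entry_date = 0, exit_date = 45,
                        exit_type = "death")
  r <- exposure_rates(split_exposure(eps, under5_age_grid(),
                                     one_period(0, 2000)))
  r <- dplyr::mutate(r, person_years = pmax(person_years, 1e-6))
  r$undefined <- FALSE
  r$rate <- r$deaths / r$person_years
  expect_warning(out <- cumulate_probabilities(r), "person-years")
  expect_true(out$low_exposure)
})
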