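test_that("a surviving 2-year-old contributes exposure only up to age 2 in window 0", {
  svy <- as_days("2015-06-01")
  rec <- tibble::tibble(
    mother_id = "m", child_id = "c",
    dob_reported = svy - 2 * 365.25,
    survived = TRUE, age_at_death_days = NA_real_,
    survey_date = svy, region = "R", weight = 1
  )
  est <- suppressWarnings(estimate_fbh(rec))
  expect_equal(nrow(est), 2)
  w0 <- est[est$period == "0-4y prior", ]
  w1 <- est[est$period == "5-9y prior", ]
  expect_equal(w0$deaths, 0)
  expect_equal(w0$person_years, 2, tolerance = 1e-9)
  expect_equal(w1$person_years, 0)
  expect_equal(w0$q5y, 0)
})

test_that("children born before the window are left-truncated at the window start", {
  svy <- as_days("2015-06-01")
  rec <- tibble::tibble(
    dob_reported = svy - 6 * 365.25, survived = TRUE,
    age_at_death_days = NA_real_, survey_date = svy, region = "R"
  )
  est <- suppressWarnings(estimate_fbh(rec))
  # first year of life falls in window 1; ages 1-4 fall in window 0,
  # entered at the then-current age of 1 year
  w1 <- est[est$period == "5-9y prior", ]
  expect_equal(w1$person_years, 1, tolerance = 1e-9)
  w0 <- est[est$period == "0-4y prior", ]
  expect_equal(w0$person_years, 4, tolerance = 1e-9)
})

test_that("total contributed exposure never exceeds the survey date", {
  sc <- small_faithful_scenario(seed = 31, annual_births = 300)
  rec <- sc$fbh
  windows <- tips_windows(sc$cfg$survey_date)
  cells <- suppressMessages(split_exposure(
    tibble::tibble(
      dob = rec$dob_reported, entry_date = rec$dob_reported,
      exit_date = ifelse(rec$survived, rec$survey_date,
                         rec$dob_reported + rec$age_at_death_days),
      exit_type = ifelse(rec$survived, "censor", "death")
    ),
    under5_age_grid(), windows
  ))
  # per-record eligible exposure: min(survey, death) - max(birth, window
  # start, birth) clipped to under-5 ages, accumulated over both windows
  end_t <- pmin(rec$survey_date,
                ifelse(rec$survived, Inf, rec$dob_reported + rec$age_at_death_days),
                rec$dob_reported + 60 * DPM)
  expected <- 0
  for (w in seq_len(nrow(windows))) {
    expected <- expected +
      sum(pmax(0, pmin(end_t, windows$end[w]) -
                 pmax(rec$dob_reported, windows$start[w])))
  }
  expect_equal(sum(cells$person_years), expected / DPY, tolerance = 1e-9)
})

test_that("FBH and HDSS estimators agree under faithful reporting", {
  sc <- small_faithful_scenario(seed = 71, annual_births = 2500)
  windows <- tips_windows(sc$cfg$survey_date)
  hdss <- estimate_hdss(sc$eps, periods = windows)
  fbh <- estimate_fbh(sc$fbh)
  n <- sc$pop$truth$births / 3 # births contributing per 5-year window
  for (qn in c("q28d", "qpnn", "q12m", "qchild", "q5y")) {
    for (w in windows$period) {
      h <- hdss[[qn]][hdss$period == w]
      f <- fbh[[qn]][fbh$period == w]
      expect_lt(abs(h - f), 3 * sqrt(2) * binom_se((h + f) / 2, n))
    }
  }
})

test_that("constant weights leave rates unchanged; mixed weights follow hand sums", {
  svy <- as_days("2015-01-01")
  rec <- tibble::tibble(
    dob_reported = svy - c(400, 700, 900, 1500, 300),
    survived = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    age_at_death_days = c(NA, 500, NA, 100, NA),
    survey_date = svy, region = "R",
    weight = 1
  )
  base <- suppressWarnings(estimate_fbh(rec))
  rec2 <- dplyr::mutate(rec, weight = 2)
  doubled <- suppressWarnings(estimate_fbh(rec2))
  for (qn in c("q28d", "qpnn", "q12m", "qchild", "q5y")) {
    expect_equal(doubled[[qn]], base[[qn]], tolerance = 1e-12)
  }
  expect_equal(doubled$deaths, 2 * base$deaths)
  expect_equal(doubled$person_years, 2 * base$person_years, tolerance = 1e-12)

  # mixed weights: weighted death count in window 0 accumulated by hand
  recw <- dplyr::mutate(rec, weight = c(1, 2, 1.5, 3, 1))
  cells <- suppressMessages(split_exposure(
    tibble::tibble(
      dob = recw$dob_reported, entry_date = recw$dob_reported,
      exit_date = ifelse(recw$survived, svy, recw$dob_reported + recw$age_at_death_days),
      exit_type = ifelse(recw$survived, "censor", "death"),
      weight = recw$weight
    ),
    under5_age_grid(), tips_windows(svy)
  ))
  # deaths: child 2 (w=2) died at 500d (12-23m seg) 200d after dob, inside
  # window 0; child 4 (w=3) died at 100d, 1400d before survey, window 0,
  # segment 3-4m
  d_12_23 <- cells$deaths[cells$age_segment == "12-23m" &
                            cells$period == "0-4y prior"]
  d_3_4 <- cells$deaths[cells$age_segment == "3-4m" &
                          cells$period == "0-4y prior"]
  expect_equal(d_12_23, 2)
  expect_equal(d_3_4, 3)
  expect_error(suppressWarnings(estimate_fbh(dplyr::mutate(rec, weight = -1))),
               "Negative weight")
})

test_that("upward heaping onto 12 months shifts deaths across the infancy boundary", {
  cfg0 <- sim_config(seed = 88, annual_births = 3000)
  pop <- simulate_population(cfg0)
  cfg_h <- sim_config(seed = 88, annual_births = 3000,
                      heaping_prob = c(m1 = 0, m12 = 1))
  f0 <- estimate_fbh(simulate_fbh_survey(pop, cfg0))
  fh <- estimate_fbh(simulate_fbh_survey(pop, cfg_h))
  # deaths truly at 10-11 months reported at exact age 1 year land in
  # the 12-23m segment: child mortality rises, postneonatal falls
  expect_true(all(fh$qchild > f0$qchild))
  expect_true(all(fh$qpnn < f0$qpnn))
})

test_that("degenerate child-death omission zeroes FBH child mortality", {
  cfg0 <- sim_config(seed = 60, annual_births = 2000)
  pop <- simulate_population(cfg0)
  cfg_om <- sim_config(seed = 60, annual_births = 2000,
                       omission_prob = c(neonatal = 0, postneonatal = 0, child = 1))
  fbh <- estimate_fbh(simulate_fbh_survey(pop, cfg_om))
  hdss <- estimate_hdss(apply_surveillance(pop, cfg0),
                        periods = tips_windows(cfg0$survey_date))
  expect_true(all(fbh$qchild == 0))
  expect_true(all(hdss$qchild > 0))
  expect_equal(rpd(hdss$qchild, fbh$qchild), rep(200, nrow(hdss)),
               tolerance = 1e-12)
})

test_that("invalid birth histories are rejected", {
  svy <- as_days("2015-01-01")
  bad_dob <- tibble::tibble(dob_reported = svy + 10, survived = TRUE,
                            age_at_death_days = NA_real_, survey_date = svy,
                            region = "R")
  expect_error(estimate_fbh(bad_dob), "after the survey date")
  bad_age <- tibble::tibble(dob_reported = svy - 100, survived = FALSE,
                            age_at_death_days = 500, survey_date = svy,
                            region = "R")
  expect_error(estimate_fbh(bad_age), "death after the survey")
})

test_that("aggregation levels group by the requested labels", {
  svy <- as_days("2015-01-01")
  rec <- tibble::tibble(
    dob_reported = svy - rep(c(400, 900), 10),
    survived = TRUE, age_at_death_days = NA_real_, survey_date = svy,
    region = rep(c("North", "South"), each = 10),
    residence = rep(c("urban", "rural"), 10)
  )
  sub <- suppressWarnings(estimate_fbh(rec, aggregation = "subnational"))
  expect_setequal(unique(sub$region), c("North", "South"))
  nat <- suppressWarnings(estimate_fbh(rec, aggregation = "national"))
  expect_false("region" %in% names(nat))
  res <- suppressWarnings(estimate_fbh(rec, aggregation = "residence"))
  expect_setequal(unique(res$residence), c("urban", "rural"))
})

test_that("survey-coded ages at death decode to day midpoints", {
  expect_equal(decode_age_at_death(c(5, 3, 1), c("days", "months", "years")),
               c(5, 3.5 * DPM, 1.5 * DPY))
})
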