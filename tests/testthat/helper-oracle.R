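# Independent oracles used across the suite. These deliberately take the
# slowest, most literal route so they share no code path with the package.

DPY <- 365.25
DPM <- 365.25 / 12

# Brute-force Lexis oracle: walks each episode calendar day by calendar
# day and, within each day, accumulates the overlap of that day with
# every age-segment x period cell directly from min/max arithmetic.
# Episodes are expected on integer-day times so the day walk is aligned.
oracle_split <- function(episodes, age_grid, periods) {
  n_seg <- length(age_grid) - 1
  labels <- attr(age_grid, "labels")
  if (is.null(labels)) labels <- paste0("seg", seq_len(n_seg))
  deaths <- matrix(0, n_seg, nrow(periods))
  py_days <- matrix(0, n_seg, nrow(periods))
  for (i in seq_len(nrow(episodes))) {
    b <- episodes$dob[i]
    s <- episodes$entry_date[i]
    e <- episodes$exit_date[i]
    if (e > s) {
      for (d in seq(floor(s), ceiling(e) - 1)) {
        for (p in seq_len(nrow(periods))) {
          for (j in seq_len(n_seg)) {
            lo <- max(d, s, b + age_grid[j], periods$start[p])
            hi <- min(d + 1, e, b + age_grid[j + 1], periods$end[p])
            if (hi > lo) py_days[j, p] <- py_days[j, p] + (hi - lo)
          }
        }
      }
    }
    if (identical(episodes$exit_type[i], "death")) {
      age <- e - b
      for (p in seq_len(nrow(periods))) {
        for (j in seq_len(n_seg)) {
          if (age >= age_grid[j] && age < age_grid[j + 1] &&
              e >= periods$start[p] && e < periods$end[p]) {
            deaths[j, p] <- deaths[j, p] + 1
          }
        }
      }
    }
  }
  out <- expand.grid(seg = seq_len(n_seg), per = seq_len(nrow(periods)))
  tibble::tibble(
    age_segment = labels[out$seg],
    period = periods$period[out$per],
    deaths = deaths[cbind(out$seg, out$per)],
    person_years = py_days[cbind(out$seg, out$per)] / DPY
  )
}

# Random integer-day episodes straddling age and period boundaries.
random_episodes <- function(n, seed, t0 = 0, t1 = 4000) {
  withr::with_seed(seed, {
    dob <- sample(t0:t1, n, replace = TRUE)
    entry_off <- ifelse(runif(n) < 0.7, 0, sample(0:400, n, replace = TRUE))
    dur <- sample(1:2500, n, replace = TRUE)
    tibble::tibble(
      dob = as.numeric(dob),
      entry_date = as.numeric(dob + entry_off),
      entry_type = ifelse(entry_off == 0, "birth", "in-migration"),
      exit_date = as.numeric(dob + entry_off + dur),
      exit_type = sample(c("death", "out-migration", "censor"), n,
                         replace = TRUE, prob = c(0.3, 0.3, 0.4))
    )
  })
}

# Normal-equations OLS oracle: solve (X'X) beta = X'y directly and build
# SEs, t p-values, R2, F from first principles.
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  n <- nrow(X); p <- ncol(X)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(s2 * solve(XtX)))
  tstat <- beta / se
  pval <- 2 * pt(abs(tstat), df = n - p, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  fstat <- ((tss - rss) / (p - 1)) / (rss / (n - p))
  list(beta = as.numeric(beta), se = as.numeric(se),
       p = as.numeric(pval), r2 = r2, adj_r2 = adj, f = fstat,
       sigma = sqrt(s2))
}

# Convenience: a faithful simulated population + survey at moderate size.
small_faithful_scenario <- function(seed = 101, annual_births = 1500) {
  cfg <- sim_config(seed = seed, annual_births = annual_births,
                    start = "2000-01-01", end = "2015-01-01")
  pop <- simulate_population(cfg)
  list(cfg = cfg, pop = pop,
       eps = apply_surveillance(pop, cfg),
       fbh = simulate_fbh_survey(pop, cfg))
}

# Binomial Monte-Carlo SE for a probability estimated from n births.
binom_se <- function(q, n) sqrt(q * (1 - q) / n)

# Build a small covariate-and-comparison scenario with configurable rpd.
make_reg_data <- function(n = 12, seed = 1, rpd_fun = NULL) {
  withr::with_seed(seed, {
    covs <- tibble::tibble(
      match_id = paste0("m", seq_len(n)),
      interview_interval = sample(c(4, 6, 12), n, replace = TRUE),
      log_births = log(runif(n, 200, 5000)),
      digit_preference = runif(n, 0, 0.4),
      pregnancy_reporting = rbinom(n, 1, 0.5),
      dhs_quality = rnorm(n),
      adult_mortality = runif(n, 0.1, 0.4),
      malaria_pr = runif(n, 0, 0.6),
      african_region = sample(c("Eastern", "Western", "Southern"), n,
                              replace = TRUE)
    )
    covs$african_region[1:3] <- c("Eastern", "Western", "Southern")
    y <- if (is.null(rpd_fun)) rnorm(n, 0, 10) else rpd_fun(covs)
    records <- tibble::tibble(
      match_id = covs$match_id, quantity = factor("qpnn", levels = Q <- c(
        "q28d", "qpnn", "q12m", "qchild", "q5y")),
      period = "0-4y prior", rpd = y
    )
  })
  list(records = records, covs = covs)
}

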