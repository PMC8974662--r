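#' Log-quadratic under-5 age-pattern model
#'
#' The two-dimensional model of under-5 mortality age patterns: for each
#' model age `x` below 5 years,
#' `ln q(x) = a(x) + b(x) ln q(5y) + c(x) (ln q(5y))^2 + v(x) k`,
#' where `q(5y)` sets the overall level and the scalar `k` modifies the
#' shape of the age pattern (scaled so that `k` has unit variance across
#' the fitting tables). At `x = 5y` the model is the identity
#' (`a = c = v = 0`, `b = 1`) by construction.
#'
#' The sign of `v` is oriented so that larger `k` means an older age
#' pattern: higher child mortality relative to infant mortality at a given
#' level (`v` at 12 months is non-positive).
#'
#' @param coefficients Tibble with columns `age_days`, `a`, `b`, `c`, `v`;
#'   the last row must be age 60 months with `a = c = v = 0`, `b = 1`.
#' @param level_range Valid range of `q5y` for prediction and level
#'   solving.
#' @return An object of class `logquad_model`.
#' @seealso [fit_logquad()], [predict_logquad()], [solve_level()],
#'   [indirect_curves()], [default_logquad()]
#' @export
logquad_model <- function(coefficients, level_range = c(0.005, 0.35)) {
  need <- c("age_days", "a", "b", "c", "v")
  if (!all(need %in% names(coefficients))) {
    abort("`coefficients` needs columns age_days, a, b, c, v.")
  }
  coefficients <- dplyr::arrange(coefficients, .data$age_days)
  last <- nrow(coefficients)
  y5 <- 60 * DAYS_PER_MONTH
  if (abs(coefficients$age_days[last] - y5) > 1e-6) {
    abort("The last model age must be 60 months.")
  }
  cl <- coefficients[last, ]
  if (any(abs(c(cl$a, cl$b - 1, cl$c, cl$v)) > 1e-10)) {
    abort("At x = 5y the model must satisfy a = 0, b = 1, c = 0, v = 0.")
  }
  structure(
    list(coefficients = coefficients, level_range = as.numeric(level_range)),
    class = "logquad_model"
  )
}

#' @export
print.logquad_model <- function(x, ...) {
  cat("<logquad_model>", nrow(x$coefficients), "model ages; valid q5y in [",
      x$level_range[1], ",", x$level_range[2], "]\n")
  invisible(x)
}

#' @describeIn logquad_model Coefficient table (one row per model age).
#' @param x A `logquad_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.logquad_model <- function(x, ...) x$coefficients

#' @describeIn logquad_model One-row model summary.
#' @exportS3Method generics::glance
glance.logquad_model <- function(x, ...) {
  tibble::tibble(
    n_ages = nrow(x$coefficients),
    level_lo = x$level_range[1],
    level_hi = x$level_range[2],
    n_tables = length(x$scores %||% NA_real_)
  )
}

#' Packaged default log-quadratic model
#'
#' Loads the synthetic coefficient set shipped with the package
#' (`inst/extdata/logquad_coefficients_synthetic.csv`). These
#' coefficients are a synthetic stand-in calibrated to a plausible
#' vital-statistics age pattern of under-5 mortality; they are intended
#' for demonstrations and for generating test life tables, not for
#' substantive inference.
#'
#' @return A [logquad_model()].
#' @export
default_logquad <- function() {
  path <- system.file("extdata", "logquad_coefficients_synthetic.csv",
                      package = "u5mcompare", mustWork = TRUE)
  coefs <- readr::read_csv(path, show_col_types = FALSE)
  logquad_model(coefs)
}

#' Fit the log-quadratic model from life tables
#'
#' Two-stage fit. Stage 1: for each model age `x`, ordinary least squares
#' of `ln q(x)` on `1`, `ln q5y`, and `(ln q5y)^2` across tables gives
#' `a(x)`, `b(x)`, `c(x)`. Stage 2: the shape vector `v(x)` is the first
#' singular direction of the residual matrix (tables x ages), scaled so
#' the per-table shape scores `k` have unit sample variance, and oriented
#' so larger `k` means an older age pattern. The `x = 5y` identity
#' constraint is imposed exactly.
#'
#' @param life_tables Long tibble with columns `table_id`, `age_days`,
#'   `q`; every table must include age 60 months (the level) and share the
#'   same set of model ages. At least 20 tables spanning at least 3
#'   distinct levels are required.
#' @param min_tables Minimum number of tables (default 20).
#' @return A [logquad_model()] with per-table shape scores in `$scores`.
#' @examples
#' lt <- synthetic_life_tables(n = 40, seed = 1)
#' fit <- fit_logquad(lt)
#' @export
fit_logquad <- function(life_tables, min_tables = 20) {
  need <- c("table_id", "age_days", "q")
  if (!all(need %in% names(life_tables))) {
    abort("`life_tables` needs columns table_id, age_days, q.")
  }
  if (any(life_tables$q <= 0 | life_tables$q >= 1)) {
    abort("All q must lie in (0, 1).")
  }
  y5 <- 60 * DAYS_PER_MONTH
  wide <- life_tables |>
    dplyr::arrange(.data$age_days) |>
    tidyr::pivot_wider(id_cols = "table_id", names_from = "age_days",
                       values_from = "q")
  ages <- as.numeric(setdiff(names(wide), "table_id"))
  if (!any(abs(ages - y5) < 1e-6)) abort("Every table must include q at 60 months.")
  Q <- as.matrix(wide[, -1])
  if (anyNA(Q)) abort("All tables must share the same set of model ages.")
  n <- nrow(Q)
  if (n < min_tables) {
    abort(paste0("Need at least ", min_tables, " life tables; got ", n, "."))
  }
  L <- log(Q[, which(abs(ages - y5) < 1e-6)])
  if (length(unique(round(L, 12))) < 3) {
    abort("Rank-deficient design: need at least 3 distinct levels of q5y to identify the quadratic.")
  }

  X <- cbind(1, L, L^2)
  idx5 <- which(abs(ages - y5) < 1e-6)
  other <- setdiff(seq_along(ages), idx5)
  abc <- matrix(0, length(ages), 3)
  abc[idx5, ] <- c(0, 1, 0)
  resid <- matrix(0, n, length(ages))
  for (j in other) {
    f <- lm.fit(X, log(Q[, j]))
    abc[j, ] <- f$coefficients
    resid[, j] <- f$residuals
  }

  sv <- svd(resid)
  k_raw <- sv$u[, 1] * sv$d[1]
  s <- sd(k_raw)
  if (s < 1e-12) {
    v <- rep(0, length(ages))
    k <- rep(0, n)
  } else {
    v <- sv$v[, 1] * s
    k <- k_raw / s
  }
  v[idx5] <- 0
  idx12 <- which.min(abs(ages - 12 * DAYS_PER_MONTH))
  if (v[idx12] > 0) {
    v <- -v
    k <- -k
  }

  model <- logquad_model(
    tibble::tibble(age_days = ages, a = abc[, 1], b = abc[, 2],
                   c = abc[, 3], v = v),
    level_range = range(exp(L))
  )
  model$scores <- setNames(k, wide$table_id)
  model
}

# ln q(x) at a single model age, vectorized over level/k
lnq_at_age <- function(model, age_days, log_q5y, k) {
  cf <- model$coefficients
  j <- which(abs(cf$age_days - age_days) < 1e-6)
  if (length(j) != 1) {
    abort(paste0("Age ", age_days, " days is not a model age."))
  }
  cf$a[j] + cf$b[j] * log_q5y + cf$c[j] * log_q5y^2 + cf$v[j] * k
}

#' Predict the under-5 age pattern from level and shape
#'
#' Evaluates `q(x) = exp(a + b ln q5y + c (ln q5y)^2 + v k)` at every
#' model age. At `x = 5y` the output equals the input level exactly.
#'
#' @param model A [logquad_model()].
#' @param q5y Level of under-5 mortality, within the model's valid range.
#' @param k Shape parameter (default 0, the central pattern).
#' @return Tibble with columns `age_days`, `q`.
#' @examples
#' predict_logquad(default_logquad(), q5y = 0.1)
#' @export
predict_logquad <- function(model, q5y, k = 0) {
  stopifnot(inherits(model, "logquad_model"), length(q5y) == 1, length(k) == 1)
  if (q5y < model$level_range[1] || q5y > model$level_range[2]) {
    abort("`q5y` outside the model's valid level range.")
  }
  L <- log(q5y)
  cf <- model$coefficients
  q <- exp(cf$a + cf$b * L + cf$c * L^2 + cf$v * k)
  # the x = 5y identity holds exactly, not through exp(log(q5y))
  q[abs(cf$age_days - 60 * DAYS_PER_MONTH) < 1e-6] <- q5y
  tibble::tibble(age_days = cf$age_days, q = q)
}

#' Solve the under-5 level from a single probability
#'
#' Inverts the model: finds the level `q5y` at which the predicted `q`
#' at age `x` (for shape `k`) equals a target value, by bisection on
#' `ln q5y` to a relative error below `tol`. Monotonicity of the
#' age-specific quadratic over the search bracket is verified first.
#'
#' @param model A [logquad_model()].
#' @param age_days Model age of the target probability.
#' @param q_target Target probability at that age.
#' @param k Shape parameter.
#' @param tol Relative error tolerance (default 1e-10).
#' @return The solved `q5y`.
#' @examples
#' m <- default_logquad()
#' solve_level(m, 365.25, predict_logquad(m, 0.1)$q[4])
#' @export
solve_level <- function(model, age_days, q_target, k = 0, tol = 1e-10) {
  stopifnot(length(q_target) == 1, q_target > 0, q_target < 1)
  cf <- model$coefficients
  j <- which(abs(cf$age_days - age_days) < 1e-6)
  if (length(j) != 1) abort(paste0("Age ", age_days, " days is not a model age."))
  lo <- log(model$level_range[1])
  hi <- log(model$level_range[2])
  # d lnq / d lnq5y = b + 2 c L must keep one sign over the bracket
  d_lo <- cf$b[j] + 2 * cf$c[j] * lo
  d_hi <- cf$b[j] + 2 * cf$c[j] * hi
  if (d_lo <= 0 || d_hi <= 0) {
    abort("Prediction at this age is not monotone increasing over the level bracket.")
  }
  f <- function(L) lnq_at_age(model, age_days, L, k) - log(q_target)
  f_lo <- f(lo); f_hi <- f(hi)
  if (f_lo > 0 || f_hi < 0) {
    abort("Target probability outside the image of the model over the valid level range.")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol * abs(log(q_target))) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  exp((lo + hi) / 2)
}

#' Indirect estimation curves from anchored probabilities
#'
#' Reproduces the indirect procedure for plotting model age-pattern
#' bounds: for each predefined anchor value (neonatal mortality q(28d),
#' or infant mortality q(12m)) and each shape parameter, solve the
#' under-5 level, predict the next-broader probability (infant, or
#' under-5), and derive the complementary quantity --- postneonatal
#' mortality (infant minus neonatal under `measure = "subtraction"`, or
#' `(infant - neonatal)/(1 - neonatal)` under `"conditional"`), or child
#' mortality (`q5y - q12m`, or `1 - (1 - q5y)/(1 - q12m)`).
#'
#' @param model A [logquad_model()].
#' @param values Predefined anchor probabilities (all within the model's
#'   image for the anchor age).
#' @param anchor `"neonatal"` (anchor q(28d), derive postneonatal) or
#'   `"infant"` (anchor q(12m), derive child).
#' @param k_set Named numeric vector of shape parameters; defaults to the
#'   central pattern and inner (+/-1) and outer (+/-2) bounds.
#' @param measure `"subtraction"` (default) or `"conditional"`.
#' @return Tibble with columns `anchor`, `anchor_value`, `role`, `k`,
#'   `q5y` (solved level), `predicted` (infant or under-5 q), `derived`
#'   (postneonatal or child q).
#' @export
indirect_curves <- function(model, values,
                            anchor = c("neonatal", "infant"),
                            k_set = c("central" = 0, "inner-lower" = -1,
                                      "inner-upper" = 1, "outer-lower" = -2,
                                      "outer-upper" = 2),
                            measure = c("subtraction", "conditional")) {
  anchor <- match.arg(anchor)
  measure <- match.arg(measure)
  anchor_age <- if (anchor == "neonatal") 28 else 12 * DAYS_PER_MONTH
  out_age <- if (anchor == "neonatal") 12 * DAYS_PER_MONTH else 60 * DAYS_PER_MONTH

  grid <- tidyr::expand_grid(
    anchor_value = values,
    tibble::tibble(role = names(k_set), k = unname(k_set))
  )
  purrr::pmap(grid, function(anchor_value, role, k) {
    lvl <- solve_level(model, anchor_age, anchor_value, k)
    pred <- predict_logquad(model, lvl, k)
    p_out <- pred$q[abs(pred$age_days - out_age) < 1e-6]
    derived <- if (measure == "subtraction") {
      p_out - anchor_value
    } else {
      (p_out - anchor_value) / (1 - anchor_value)
    }
    tibble::tibble(
      anchor = anchor, anchor_value = anchor_value, role = role, k = k,
      q5y = lvl, predicted = p_out, derived = derived
    )
  }) |>
    dplyr::bind_rows()
}

#' Generate synthetic vital-statistics life tables
#'
#' Draws life tables from a log-quadratic model with known level, shape,
#' and optional log-scale Gaussian noise --- the generative counterpart of
#' [fit_logquad()], used for testing coefficient recovery and as the
#' packaged stand-in for registration-based life-table collections.
#'
#' Shape scores are drawn Gaussian and, when `orthogonalize = TRUE`
#' (default), residualized against the stage-1 design and standardized to
#' unit sample variance, so that a noiseless fit recovers the generating
#' coefficients exactly.
#'
#' @param n Number of tables.
#' @param model Generating [logquad_model()] (default: the packaged one).
#' @param q5y_range Range of levels, spread log-uniformly.
#' @param k_sd Shape score standard deviation before standardization.
#' @param noise_sd Log-scale Gaussian noise standard deviation.
#' @param orthogonalize Residualize and standardize the shape scores
#'   (exact-recovery normalization).
#' @param seed Integer seed.
#' @return Long tibble: `table_id`, `age_days`, `q`, with true scores in
#'   attribute `"k"`.
#' @export
synthetic_life_tables <- function(n = 40, model = default_logquad(),
                                  q5y_range = c(0.01, 0.3), k_sd = 1,
                                  noise_sd = 0, orthogonalize = TRUE,
                                  seed = 1) {
  withr::with_seed(seed, {
    L <- log(q5y_range[1]) +
      (seq_len(n) - 1) / (n - 1) * (log(q5y_range[2]) - log(q5y_range[1]))
    k <- stats::rnorm(n, 0, k_sd)
    if (orthogonalize && sd(k) > 0) {
      X <- cbind(1, L, L^2)
      k <- lm.fit(X, k)$residuals
      k <- k / sd(k)
    }
    cf <- model$coefficients
    tabs <- purrr::map(seq_len(n), function(i) {
      lnq <- cf$a + cf$b * L[i] + cf$c * L[i]^2 + cf$v * k[i] +
        ifelse(abs(cf$age_days - 60 * DAYS_PER_MONTH) < 1e-6, 0,
               stats::rnorm(nrow(cf), 0, noise_sd))
      tibble::tibble(table_id = sprintf("T%03d", i), age_days = cf$age_days,
                     q = exp(lnq))
    })
    out <- dplyr::bind_rows(tabs)
    attr(out, "k") <- k
    out
  })
}
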