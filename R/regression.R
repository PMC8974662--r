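#' Assemble a regression design from comparison records and covariates
#'
#' Joins the relative-difference records for one mortality quantity to a
#' covariate table (by `match_id` and, when present in both, `period`),
#' keeps complete cases only (dropped rows are noted), turns an
#' `african_region` column into a factor with Eastern as the reference
#' level, and derives a `tips_59` dummy (1 for the 5--9-years-prior
#' window) from the period label when not supplied.
#'
#' @param records Comparison records from [match_compare()].
#' @param covariates Covariate tibble keyed by `match_id` (and optionally
#'   `period`).
#' @param response_quantity One of `"q28d"`, `"qpnn"`, `"q12m"`,
#'   `"qchild"`, `"q5y"`.
#' @param terms Character vector of covariate names to include.
#' @return List with `data` (complete-case analysis tibble with `rpd`
#'   response), `formula`, and `n_dropped`.
#' @export
build_design <- function(records, covariates, response_quantity,
                         terms) {
  stopifnot(response_quantity %in% Q_NAMES)
  keys <- intersect(intersect(c("match_id", "period"), names(records)),
                    names(covariates))
  if (!"match_id" %in% keys) abort("`covariates` must carry `match_id`.")
  df <- records |>
    dplyr::filter(.data$quantity == response_quantity) |>
    dplyr::inner_join(covariates, by = keys)
  if ("tips_59" %in% terms && !"tips_59" %in% names(df)) {
    if (!"period" %in% names(df)) abort("Cannot derive `tips_59` without a period label.")
    df$tips_59 <- as.integer(grepl("5-9", df$period))
  }
  missing_terms <- setdiff(terms, names(df))
  if (length(missing_terms) > 0) {
    abort(paste0("Covariate(s) not found: ", paste(missing_terms, collapse = ", ")))
  }
  if ("african_region" %in% terms) {
    df$african_region <- stats::relevel(factor(df$african_region), ref = "Eastern")
  }
  keep_cols <- c("rpd", terms)
  cc <- complete.cases(df[, keep_cols])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " row(s) with missing response or covariates dropped."))
  }
  list(
    data = df[cc, , drop = FALSE],
    formula = stats::reformulate(terms, response = "rpd"),
    n_dropped = n_dropped
  )
}

#' OLS regression of relative differences on covariates
#'
#' Ordinary least squares of the relative percentage difference between
#' surveillance and survey estimates on fieldwork, context, and quality
#' covariates, for one mortality quantity. Coefficient standard errors
#' use the unbiased residual variance; p-values are two-sided from the t
#' distribution; the F statistic tests against the intercept-only model.
#'
#' @inheritParams build_design
#' @param model `"bivariate"` (each single covariate) is a convenience
#'   label; the fit simply uses the covariates in `terms`.
#' @return Object of class `rpd_ols` (wrapping the `lm` fit) with
#'   [tidy()] and [glance()] methods.
#' @examples
#' \dontrun{
#' fit <- rpd_ols(records, covs, "qpnn", c("interview_interval"))
#' tidy(fit)
#' }
#' @export
rpd_ols <- function(records, covariates, response_quantity, terms) {
  design <- build_design(records, covariates, response_quantity, terms)
  n <- nrow(design$data)
  p <- length(terms)
  if (n <= p + 1) abort("Not enough complete cases for the requested model.")
  fit <- lm(design$formula, data = design$data)
  if (any(is.na(coef(fit)))) {
    abort("Rank-deficient design: some covariates are collinear.")
  }
  structure(
    list(fit = fit, response_quantity = response_quantity,
         terms = terms, n_dropped = design$n_dropped),
    class = "rpd_ols"
  )
}

#' @export
print.rpd_ols <- function(x, ...) {
  cat("<rpd_ols> response: RPD in", x$response_quantity, "| n =",
      stats::nobs(x$fit), "\n")
  print(tidy(x))
  invisible(x)
}

#' @describeIn rpd_ols Coefficient table: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @param x An `rpd_ols` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rpd_ols <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @describeIn rpd_ols Model-level summary: R-squared, adjusted
#'   R-squared, residual SE, F statistic with degrees of freedom, n.
#' @exportS3Method generics::glance
glance.rpd_ols <- function(x, ...) {
  s <- summary(x$fit)
  fs <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = if (is.null(fs)) NA_real_ else unname(fs[1]),
    df = if (is.null(fs)) NA_real_ else unname(fs[2]),
    df.residual = s$df[2],
    p.value = if (is.null(fs)) NA_real_ else unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    nobs = stats::nobs(x$fit)
  )
}

#' Bivariate covariate screen
#'
#' Fits one bivariate model per candidate covariate and flags those whose
#' association with the response clears a p-value threshold (any
#' coefficient of the covariate, for categorical terms). The threshold
#' implements the "strongly associated" inclusion rule for multivariable
#' models as an explicit, adjustable flag.
#'
#' @inheritParams build_design
#' @param candidates Character vector of candidate covariates.
#' @param threshold Inclusion p-value threshold (default 0.10).
#' @return Tibble with one row per candidate x coefficient: `covariate`,
#'   `term`, `estimate`, `std.error`, `p.value`, `selected`.
#' @export
bivariate_screen <- function(records, covariates, response_quantity,
                             candidates, threshold = 0.10) {
  purrr::map(candidates, function(cand) {
    fit <- rpd_ols(records, covariates, response_quantity, cand)
    td <- dplyr::filter(tidy(fit), .data$term != "(Intercept)")
    dplyr::mutate(td, covariate = cand,
                  selected = any(td$p.value < threshold),
                  .before = 1)
  }) |>
    dplyr::bind_rows()
}
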