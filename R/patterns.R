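#' Age-pattern ratios from probability sets
#'
#' Computes the two summary ratios of the under-5 age pattern: child-to-
#' infant mortality `qchild / q12m` and postneonatal-to-neonatal mortality
#' `qpnn / q28d`. Ratios with a zero denominator are flagged undefined
#' (`NA` with `undefined_* = TRUE`) rather than returned as infinities.
#' Sources reporting only abridged quantities (no neonatal split, e.g.
#' registration-based life tables) get an undefined neonatal ratio.
#'
#' @param probability_sets Tibble with columns `q28d`, `qpnn`, `q12m`,
#'   `qchild` (label columns such as `source`, `region`, `subregion`,
#'   `period` are carried through).
#' @return The input plus `ratio_child_infant`, `ratio_pnn_nn`,
#'   `undefined_child_infant`, `undefined_pnn_nn`.
#' @examples
#' mortality_ratios(tibble::tibble(
#'   q28d = 0.02, qpnn = 0.03, q12m = 0.0494, qchild = 0.04
#' ))
#' @export
mortality_ratios <- function(probability_sets) {
  ps <- probability_sets
  if (!"q28d" %in% names(ps)) ps$q28d <- NA_real_
  if (!"qpnn" %in% names(ps)) ps$qpnn <- NA_real_
  dplyr::mutate(
    ps,
    undefined_child_infant = is.na(.data$q12m) | .data$q12m == 0,
    undefined_pnn_nn = is.na(.data$q28d) | .data$q28d == 0,
    ratio_child_infant = dplyr::if_else(.data$undefined_child_infant,
                                        NA_real_, .data$qchild / .data$q12m),
    ratio_pnn_nn = dplyr::if_else(.data$undefined_pnn_nn,
                                  NA_real_, .data$qpnn / .data$q28d)
  )
}

#' Grouped median/IQR summaries
#'
#' Median, interquartile range, and count per group, using the
#' linear-interpolation quantile rule (R type 7). Groups with fewer than
#' 3 observations are flagged as small.
#'
#' @param data Tibble of values to summarize.
#' @param value Name of the value column (string).
#' @param by Character vector of grouping columns (e.g.
#'   `c("source", "subregion")`).
#' @return Tibble with one row per group: grouping columns, `n`, `median`,
#'   `q25`, `q75`, `iqr`, `small_group`.
#' @examples
#' group_summary(tibble::tibble(g = "a", x = 1:5), "x", "g")
#' @export
group_summary <- function(data, value, by = character(0)) {
  vals <- data[[value]]
  if (is.null(vals)) abort(paste0("No column `", value, "` in `data`."))
  data |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data[[value]]),
      q25 = quantile(.data[[value]], 0.25, type = 7, names = FALSE),
      q75 = quantile(.data[[value]], 0.75, type = 7, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(iqr = .data$q75 - .data$q25, small_group = .data$n < 3)
}

#' Nonparametric test of difference in medians
#'
#' Mood's median test: observations from both samples are pooled, each is
#' classified as above or not-above the pooled median, and the resulting
#' 2x2 contingency table is tested with a continuity-corrected chi-square
#' test. When any cell's expected count is below 5 (or either sample has
#' fewer than 2 observations), Fisher's exact test is used instead, with
#' a warning for the degenerate single-observation case.
#'
#' @param x Numeric sample of interest.
#' @param reference Reference sample (e.g. the survey-based medians).
#' @return Tibble with `statistic` (chi-square; `NA` under the exact
#'   fallback), `p_value`, `method`, `n_x`, `n_ref`.
#' @examples
#' median_test(c(5, 6, 7, 8), c(1, 2, 3, 4))
#' @export
median_test <- function(x, reference) {
  x <- x[!is.na(x)]
  reference <- reference[!is.na(reference)]
  if (length(x) == 0 || length(reference) == 0) {
    abort("Both samples must be nonempty.")
  }
  pooled <- median(c(x, reference))
  tab <- rbind(
    c(sum(x > pooled), sum(x <= pooled)),
    c(sum(reference > pooled), sum(reference <= pooled))
  )
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  degenerate <- min(length(x), length(reference)) < 2
  if (degenerate) {
    warn("A sample has fewer than 2 observations; falling back to Fisher's exact test.")
  }
  if (degenerate || any(expected < 5)) {
    ft <- fisher.test(tab)
    out <- tibble::tibble(statistic = NA_real_, p_value = ft$p.value,
                          method = "fisher-exact")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
    out <- tibble::tibble(statistic = unname(ct$statistic),
                          p_value = ct$p.value,
                          method = "mood-chisq")
  }
  dplyr::mutate(out, n_x = length(x), n_ref = length(reference))
}

#' Rank-sum alternative to the median test
#'
#' Wilcoxon rank-sum test on the same interface as [median_test()], for
#' sensitivity to the choice of nonparametric test.
#'
#' @inheritParams median_test
#' @return Tibble with `statistic`, `p_value`, `method`, `n_x`, `n_ref`.
#' @export
ranksum_test <- function(x, reference) {
  x <- x[!is.na(x)]
  reference <- reference[!is.na(reference)]
  if (length(x) == 0 || length(reference) == 0) {
    abort("Both samples must be nonempty.")
  }
  wt <- suppressWarnings(stats::wilcox.test(x, reference))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = "wilcoxon-ranksum", n_x = length(x),
                 n_ref = length(reference))
}

#' Ratio summaries with median tests against a reference source
#'
#' Groups ratio records by source (and optional strata), summarizes each
#' group with median/IQR, and tests each group's values against the
#' reference source's values within the same stratum.
#'
#' @param ratio_records Output of [mortality_ratios()] with a `source`
#'   column.
#' @param value Ratio column to summarize (default child-to-infant).
#' @param by Extra stratum columns beyond `source`.
#' @param reference Reference source label (default `"DHS"`).
#' @param test `"median"` (Mood) or `"ranksum"` (Wilcoxon).
#' @return [group_summary()] table with appended `p_value` vs the
#'   reference (`NA` for the reference rows themselves).
#' @export
ratio_comparison <- function(ratio_records, value = "ratio_child_infant",
                             by = character(0), reference = "DHS",
                             test = c("median", "ranksum")) {
  test <- match.arg(test)
  test_fun <- if (test == "median") median_test else ranksum_test
  summ <- group_summary(ratio_records, value, by = c("source", by))
  if (!reference %in% ratio_records$source) {
    warn(paste0("Reference source '", reference, "' absent; no tests run."))
    return(dplyr::mutate(summ, p_value = NA_real_))
  }
  pvals <- purrr::pmap_dbl(summ, function(...) {
    row <- list(...)
    if (identical(row$source, reference)) return(NA_real_)
    sel <- ratio_records$source == row$source
    ref <- ratio_records$source == reference
    for (col in by) {
      sel <- sel & ratio_records[[col]] == row[[col]]
      ref <- ref & ratio_records[[col]] == row[[col]]
    }
    vx <- ratio_records[[value]][sel]
    vr <- ratio_records[[value]][ref]
    if (sum(!is.na(vx)) == 0 || sum(!is.na(vr)) == 0) return(NA_real_)
    test_fun(vx, vr)$p_value
  })
  dplyr::mutate(summ, p_value = pvals)
}
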