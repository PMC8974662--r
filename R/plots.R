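#' Scatter plot of the under-5 age pattern
#'
#' Infant mortality q(12m) against child mortality q(12m,5y) by source,
#' optionally overlaid with log-quadratic model curves for a set of shape
#' parameters (solid central pattern, dashed inner and dotted outer
#' bounds).
#'
#' @param probability_sets Tibble with `q12m`, `qchild`, and a `source`
#'   column.
#' @param model Optional [logquad_model()] for overlay curves.
#' @param k_set Shape parameters for the overlay.
#' @return A ggplot object.
#' @export
plot_age_pattern <- function(probability_sets, model = NULL,
                             k_set = c("central" = 0, "inner-lower" = -1,
                                       "inner-upper" = 1, "outer-lower" = -2,
                                       "outer-upper" = 2)) {
  p <- ggplot2::ggplot(probability_sets,
                       ggplot2::aes(x = .data$q12m, y = .data$qchild)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$source), alpha = 0.7) +
    ggplot2::labs(x = "Infant mortality q(12m)",
                  y = "Child mortality q(12m,5y)") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    levels <- exp(seq(log(model$level_range[1] * 1.02),
                      log(model$level_range[2] * 0.98), length.out = 40))
    curves <- purrr::map(seq_along(k_set), function(i) {
      pts <- purrr::map(levels, function(l) {
        pr <- predict_logquad(model, l, k_set[i])
        tibble::tibble(
          q12m = pr$q[abs(pr$age_days - 12 * DAYS_PER_MONTH) < 1e-6],
          qchild = 1 - (1 - l) /
            (1 - pr$q[abs(pr$age_days - 12 * DAYS_PER_MONTH) < 1e-6])
        )
      })
      dplyr::bind_rows(pts) |>
        dplyr::mutate(role = names(k_set)[i])
    }) |>
      dplyr::bind_rows()
    curves$linetype <- ifelse(curves$role == "central", "solid",
                              ifelse(grepl("inner", curves$role), "dashed", "dotted"))
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$q12m, y = .data$qchild, group = .data$role,
                   linetype = .data$linetype),
      colour = "black", linewidth = 0.4, show.legend = FALSE
    ) + ggplot2::scale_linetype_identity()
  }
  p
}

#' Box plots of age-pattern ratios by source
#'
#' @param ratio_records Output of [mortality_ratios()] with a `source`
#'   column.
#' @param value Ratio column (default child-to-infant).
#' @return A ggplot object.
#' @export
plot_ratio_box <- function(ratio_records, value = "ratio_child_infant") {
  ggplot2::ggplot(ratio_records,
                  ggplot2::aes(x = .data$source, y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.alpha = 0.5) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}

#' Box plots of relative percentage differences by quantity
#'
#' @param records Comparison records from [match_compare()].
#' @return A ggplot object.
#' @export
plot_rpd <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$quantity, y = .data$rpd)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_boxplot(outlier.alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "Relative % difference (surveillance - survey)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.logquad_model <- function(object, q5y = NULL, ...) {
  q5y <- q5y %||% exp(mean(log(object$level_range)))
  ks <- c(-2, -1, 0, 1, 2)
  df <- purrr::map(ks, function(k) {
    dplyr::mutate(predict_logquad(object, q5y, k), k = k)
  }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_days / DAYS_PER_MONTH,
                                   y = .data$q, colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Age (months)", y = "Cumulative q(x)",
                  colour = "shape k",
                  title = paste0("Log-quadratic age pattern at q(5y) = ", signif(q5y, 3))) +
    ggplot2::theme_minimal()
}
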