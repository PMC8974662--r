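#' Relative percentage difference
#'
#' The comparison metric between paired estimates: the surveillance value
#' minus the survey value, divided by the average of the two, times 100.
#' Positive values mean the surveillance estimate is higher. The measure
#' is antisymmetric and bounded in `[-200, 200]` for non-negative inputs;
#' it is undefined (`NA`) when both values are zero.
#'
#' @param hdss,fbh Non-negative numeric vectors of paired estimates.
#' @return Numeric vector of relative percentage differences.
#' @examples
#' rpd(0.11, 0.10)
#' @export
rpd <- function(hdss, fbh) {
  if (any(hdss < 0 | fbh < 0, na.rm = TRUE)) abort("Estimates must be non-negative.")
  out <- 100 * (hdss - fbh) / ((hdss + fbh) / 2)
  out[hdss == 0 & fbh == 0] <- NA_real_
  out
}

Q_NAMES <- c("q28d", "qpnn", "q12m", "qchild", "q5y")

#' Match surveillance strata to survey regions and compare estimates
#'
#' Pairs surveillance (HDSS) probability sets with survey (FBH)
#' probability sets via an explicit label match table, keeps only
#' identical periods, and computes the relative percentage difference for
#' each of the five mortality quantities. Unmatched labels are skipped
#' with a note; pairs where both values are zero are dropped with a note
#' rather than emitted as undefined.
#'
#' @param hdss_sets Probability-set tibble from [estimate_hdss()] with a
#'   stratum column (default `region`).
#' @param fbh_sets Probability-set tibble from [estimate_fbh()] with a
#'   region column.
#' @param match_table Two-column tibble `hdss_label`, `fbh_label` pairing
#'   strata; default pairs identical labels present in both inputs.
#' @param hdss_stratum,fbh_stratum Names of the label columns.
#' @return Long tibble of comparison records: `match_id`, `hdss_stratum`,
#'   `fbh_region`, `period`, `quantity`, `hdss`, `fbh`, `rpd`.
#' @export
match_compare <- function(hdss_sets, fbh_sets, match_table = NULL,
                          hdss_stratum = "region", fbh_stratum = "region") {
  if (is.null(match_table)) {
    shared <- intersect(unique(hdss_sets[[hdss_stratum]]),
                        unique(fbh_sets[[fbh_stratum]]))
    match_table <- tibble::tibble(hdss_label = shared, fbh_label = shared)
  }
  stopifnot(all(c("hdss_label", "fbh_label") %in% names(match_table)))

  unmatched <- setdiff(match_table$hdss_label, hdss_sets[[hdss_stratum]])
  unmatched <- c(unmatched, setdiff(match_table$fbh_label, fbh_sets[[fbh_stratum]]))
  if (length(unmatched) > 0) {
    inform(paste0("Skipping unmatched label(s): ",
                  paste(unique(unmatched), collapse = ", ")))
  }

  h_long <- hdss_sets |>
    dplyr::select(dplyr::all_of(c(hdss_stratum, "period", Q_NAMES))) |>
    tidyr::pivot_longer(dplyr::all_of(Q_NAMES), names_to = "quantity",
                        values_to = "hdss") |>
    dplyr::rename(hdss_stratum = dplyr::all_of(hdss_stratum))
  f_long <- fbh_sets |>
    dplyr::select(dplyr::all_of(c(fbh_stratum, "period", Q_NAMES))) |>
    tidyr::pivot_longer(dplyr::all_of(Q_NAMES), names_to = "quantity",
                        values_to = "fbh") |>
    dplyr::rename(fbh_region = dplyr::all_of(fbh_stratum))

  out <- match_table |>
    dplyr::rename(hdss_stratum = "hdss_label", fbh_region = "fbh_label") |>
    dplyr::inner_join(h_long, by = "hdss_stratum",
                      relationship = "many-to-many") |>
    dplyr::inner_join(f_long, by = c("fbh_region", "period", "quantity"))

  both_zero <- out$hdss == 0 & out$fbh == 0
  if (any(both_zero)) {
    inform(paste0(sum(both_zero),
                  " pair(s) with both values zero dropped (undefined difference)."))
    out <- out[!both_zero, , drop = FALSE]
  }
  out |>
    dplyr::mutate(
      match_id = paste(.data$hdss_stratum, .data$fbh_region, sep = "~"),
      rpd = rpd(.data$hdss, .data$fbh),
      quantity = factor(.data$quantity, levels = Q_NAMES)
    ) |>
    dplyr::select("match_id", "hdss_stratum", "fbh_region", "period",
                  "quantity", "hdss", "fbh", "rpd")
}

#' Summarize relative differences by quantity
#'
#' Median, IQR, and count of relative percentage differences for each of
#' the five mortality quantities (positive medians: surveillance higher).
#'
#' @param records Comparison records from [match_compare()].
#' @param by Grouping columns (default `"quantity"`).
#' @return [group_summary()] table of the `rpd` column.
#' @export
difference_summary <- function(records, by = "quantity") {
  group_summary(records, "rpd", by = by)
}
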