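#' Read and write episode and birth-history files
#'
#' Delimited-text interchange for the two record types: one row per
#' residency spell (episode files) or per reported child (birth-history
#' files), with ISO-8601 dates. Writing quantizes the package's
#' continuous internal day numbers down to whole days; a missing
#' observation date is an empty field. Reading converts dates back to
#' internal day numbers.
#'
#' @param episodes,records Tibbles as produced by [simulate_population()]
#'   / [simulate_fbh_survey()].
#' @param path File path (`.csv`).
#' @return The read functions return a tibble; the write functions return
#'   `path` invisibly.
#' @name episode_io
NULL

DATE_COLS_EPI <- c("dob", "entry_date", "exit_date", "obs_date")
DATE_COLS_FBH <- c("dob_reported", "survey_date")

#' @rdname episode_io
#' @export
write_episodes <- function(episodes, path) {
  out <- episodes
  for (col in intersect(DATE_COLS_EPI, names(out))) {
    out[[col]] <- as_date(out[[col]])
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname episode_io
#' @export
read_episodes <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  for (col in intersect(DATE_COLS_EPI, names(out))) {
    out[[col]] <- as_days(out[[col]])
  }
  out
}

#' @rdname episode_io
#' @export
write_birth_histories <- function(records, path) {
  out <- records
  for (col in intersect(DATE_COLS_FBH, names(out))) {
    out[[col]] <- as_date(out[[col]])
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname episode_io
#' @export
read_birth_histories <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  for (col in intersect(DATE_COLS_FBH, names(out))) {
    out[[col]] <- as_days(out[[col]])
  }
  out
}

#' Read abridged life tables
#'
#' Reads a delimited life-table file into the long format used by
#' [fit_logquad()]: columns `table_id`, `age_days`, `q`.
#'
#' @param path File path (`.csv` with those three columns).
#' @return Long tibble of life-table records.
#' @export
read_life_tables <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("table_id", "age_days", "q")
  if (!all(need %in% names(out))) {
    abort("Life-table file needs columns table_id, age_days, q.")
  }
  out
}
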