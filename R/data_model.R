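# Domain types: AE episodes, patient disposition records, study-week grid.
#
# Conventions (stated here because AE listings differ between sponsors):
#   * study days are 1-based; day 1 is the first treatment day;
#   * AE intervals [start_day, end_day] are inclusive on both ends;
#   * week w covers study days [(w-1)*L + 1, w*L] for week length L (default 7).

.ae_required <- c("patient_id", "term", "grade", "start_day")
.ae_cols <- c("patient_id", "term", "grade", "start_day", "end_day", "ongoing")
.patient_cols <- c("patient_id", "arm", "last_study_day")

#' Normalize an adverse-event term
#'
#' Case-folds and trims whitespace. No synonym or MedDRA mapping is applied:
#' distinct spellings of the same medical concept remain distinct terms.
#'
#' @param x Character vector of AE terms.
#' @return Character vector of normalized terms.
#' @export
normalize_term <- function(x) {
  tolower(trimws(as.character(x)))
}

#' Construct a validated table of adverse-event episodes
#'
#' An episode is one reported TEAE interval: a patient identifier, a
#' free-text term, a CTCAE-style severity grade 1-5, a 1-based start study
#' day, and either an inclusive end study day or an ongoing flag (no
#' recorded resolution). Terms are normalized with [normalize_term()].
#'
#' @param x A data frame with columns `patient_id`, `term`, `grade`,
#'   `start_day`, and optionally `end_day` and `ongoing`. When `ongoing` is
#'   absent it is inferred as `is.na(end_day)`.
#' @return A tibble with columns `patient_id`, `term`, `grade`, `start_day`,
#'   `end_day`, `ongoing`, validated against the episode invariants.
#' @examples
#' ae_episodes(data.frame(
#'   patient_id = "P01", term = "Diarrhea", grade = 2,
#'   start_day = 8, end_day = 21
#' ))
#' @export
ae_episodes <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(.ae_required, names(x))
  if (length(missing_cols) > 0) {
    config_error(sprintf(
      "AE table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"end_day" %in% names(x)) x$end_day <- NA_integer_
  if (!"ongoing" %in% names(x)) x$ongoing <- is.na(x$end_day)

  out <- tibble::tibble(
    patient_id = as.character(x$patient_id),
    term = normalize_term(x$term),
    grade = as_integerish(x$grade),
    start_day = as_integerish(x$start_day),
    end_day = as_integerish(x$end_day),
    ongoing = parse_flag(x$ongoing)
  )

  bad <- which(is.na(out$grade) | out$grade < 1L | out$grade > 5L)
  if (length(bad) > 0) {
    validation_error(sprintf(
      "AE grade must be an integer in 1..5; invalid in row(s): %s",
      row_list(bad)
    ))
  }
  bad <- which(is.na(out$start_day) | out$start_day < 1L)
  if (length(bad) > 0) {
    validation_error(sprintf(
      "AE start_day must be an integer >= 1; invalid in row(s): %s",
      row_list(bad)
    ))
  }
  bad <- which(!is.na(out$end_day) & out$end_day < out$start_day)
  if (length(bad) > 0) {
    validation_error(sprintf(
      "AE end_day must be >= start_day; invalid in row(s): %s", row_list(bad)
    ))
  }
  bad <- which(is.na(out$end_day) & !out$ongoing)
  if (length(bad) > 0) {
    validation_error(sprintf(
      "AE episodes without an end_day must be flagged ongoing; row(s): %s",
      row_list(bad)
    ))
  }
  bad <- which(is.na(out$term) | out$term == "")
  if (length(bad) > 0) {
    validation_error(sprintf(
      "AE term must be non-empty; invalid in row(s): %s", row_list(bad)
    ))
  }
  out
}

#' Construct a validated table of patient disposition records
#'
#' One row per patient: identifier, treatment-arm label, and the last study
#' day (the final day the patient contributes observation time, hence risk-set
#' membership).
#'
#' @param x A data frame with columns `patient_id`, `arm`, `last_study_day`.
#' @param require_two_arms If `TRUE`, error unless exactly two distinct arm
#'   labels are present (the between-arm comparison requires two arms;
#'   single-arm subsets are valid inputs for arm-level series).
#' @return A validated tibble.
#' @export
patient_records <- function(x, require_two_arms = FALSE) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(.patient_cols, names(x))
  if (length(missing_cols) > 0) {
    config_error(sprintf(
      "patient table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    patient_id = as.character(x$patient_id),
    arm = trimws(as.character(x$arm)),
    last_study_day = as_integerish(x$last_study_day)
  )
  dup <- unique(out$patient_id[duplicated(out$patient_id)])
  if (length(dup) > 0) {
    validation_error(sprintf(
      "duplicate patient_id(s) in patient table: %s",
      paste(head(dup, 5L), collapse = ", ")
    ))
  }
  bad <- which(is.na(out$last_study_day) | out$last_study_day < 1L)
  if (length(bad) > 0) {
    validation_error(sprintf(
      "last_study_day must be an integer >= 1; invalid in row(s): %s",
      row_list(bad)
    ))
  }
  bad <- which(is.na(out$arm) | out$arm == "")
  if (length(bad) > 0) {
    validation_error(sprintf(
      "arm label must be non-empty; invalid in row(s): %s", row_list(bad)
    ))
  }
  if (require_two_arms) {
    labs <- sort(unique(out$arm))
    if (length(labs) != 2L) {
      validation_error(sprintf(
        "expected exactly two arm labels, found %d: %s",
        length(labs), paste(labs, collapse = ", ")
      ))
    }
  }
  out
}

# Parse a truthy/falsy column (logical, 0/1, yes/no, true/false, blank = FALSE)
parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  s <- tolower(trimws(as.character(x)))
  s[is.na(s)] <- ""
  truthy <- s %in% c("true", "t", "1", "yes", "y")
  falsy <- s %in% c("false", "f", "0", "no", "n", "")
  bad <- which(!truthy & !falsy)
  if (length(bad) > 0) {
    validation_error(sprintf(
      "cannot interpret ongoing flag; invalid in row(s): %s", row_list(bad)
    ))
  }
  truthy
}

# Column mapping --------------------------------------------------------------

# column_map: named character vector or list, internal name -> file column.
# Unmapped internal names default to themselves, so CDISC-like exports
# (USUBJID/AEDECOD/AETOXGR/AESTDY/AEENDY) map without editing the file.
apply_column_map <- function(df, column_map, required, optional = character()) {
  wanted <- c(required, optional)
  map <- setNames(wanted, wanted)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    unknown <- setdiff(names(column_map), wanted)
    if (length(unknown) > 0) {
      config_error(sprintf(
        "column map names unknown field(s): %s (known: %s)",
        paste(unknown, collapse = ", "), paste(wanted, collapse = ", ")
      ))
    }
    map[names(column_map)] <- column_map
  }
  for (field in required) {
    if (!map[[field]] %in% names(df)) {
      config_error(sprintf(
        "required column '%s' (mapped to field '%s') not found in file",
        map[[field]], field
      ))
    }
  }
  out <- df[intersect(unname(map), names(df))]
  present <- map[map %in% names(df)]
  names(out)[match(unname(present), names(out))] <- names(present)
  out
}

#' Read an adverse-event listing table
#'
#' Reads a delimited text file with one row per reported TEAE episode and
#' returns a validated episode table. A column map allows files whose headers
#' differ from the canonical names (for example CDISC AE exports) to be read
#' without editing.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector or list mapping internal
#'   field names (`patient_id`, `term`, `grade`, `start_day`, `end_day`,
#'   `ongoing`) to the column names used in the file.
#' @param delim Field delimiter, default comma.
#' @return A validated episode tibble (see [ae_episodes()]).
#' @export
read_ae_table <- function(path, column_map = NULL, delim = ",") {
  if (!file.exists(path)) io_error(sprintf("AE table not found: %s", path))
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  df <- apply_column_map(
    raw, column_map,
    required = .ae_required, optional = c("end_day", "ongoing")
  )
  ae_episodes(df)
}

#' Read a patient disposition table
#'
#' @inheritParams read_ae_table
#' @param column_map Optional mapping for fields `patient_id`, `arm`,
#'   `last_study_day`.
#' @param require_two_arms Passed to [patient_records()]; defaults to `TRUE`
#'   because downstream arm comparison requires exactly two arms.
#' @return A validated patient tibble.
#' @export
read_patient_table <- function(path, column_map = NULL, delim = ",",
                               require_two_arms = TRUE) {
  if (!file.exists(path)) io_error(sprintf("patient table not found: %s", path))
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  df <- apply_column_map(raw, column_map, required = .patient_cols)
  patient_records(df, require_two_arms = require_two_arms)
}

#' Write AE episodes in the canonical dialect
#'
#' Comma-separated, header row, ongoing episodes written with a blank
#' `end_day` and `ongoing = true`. Re-reading with [read_ae_table()] yields
#' identical records.
#'
#' @param episodes Episode table (coerced via [ae_episodes()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ae_table <- function(episodes, path) {
  episodes <- ae_episodes(episodes)
  out <- episodes
  out$ongoing <- ifelse(out$ongoing, "true", "false")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a patient disposition table in the canonical dialect
#'
#' @param patients Patient table (coerced via [patient_records()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(patients, path) {
  patients <- patient_records(patients)
  readr::write_csv(patients, path, na = "")
  invisible(path)
}

#' Impute end dates for ongoing adverse events
#'
#' An episode reported as ongoing at the end of the study has no resolution
#' date; its end date is imputed as the patient's last study day. Episodes
#' whose recorded end date runs past the patient's last study day are
#' truncated to it, so that no burden is counted outside the observed
#' on-study window.
#'
#' @param episodes Episode table (see [ae_episodes()]).
#' @param patients Patient table (see [patient_records()]); every episode's
#'   `patient_id` must appear here.
#' @return The episode table with a concrete `end_day` for every row.
#' @export
impute_end_dates <- function(episodes, patients) {
  episodes <- ae_episodes(episodes)
  patients <- patient_records(patients)
  unknown <- setdiff(episodes$patient_id, patients$patient_id)
  if (length(unknown) > 0) {
    validation_error(sprintf(
      "episode(s) reference unknown patient_id(s): %s",
      paste(head(unknown, 5L), collapse = ", ")
    ))
  }
  last <- patients$last_study_day[match(episodes$patient_id, patients$patient_id)]
  bad <- which(episodes$start_day > last)
  if (length(bad) > 0) {
    validation_error(sprintf(
      "episode starts after the patient's last study day in row(s): %s",
      row_list(bad)
    ))
  }
  episodes$end_day <- as.integer(pmin(
    ifelse(is.na(episodes$end_day), last, episodes$end_day), last
  ))
  episodes
}

# Study-week grid --------------------------------------------------------------

#' Define the study-week grid
#'
#' Weeks are anchored globally to study day 1 (the first treatment day):
#' week `w` covers study days `[(w-1)*L + 1, w*L]` inclusive, with
#' `L = week_length`.
#'
#' @param patients Optional patient table; when given, `n_weeks` defaults to
#'   the number of weeks needed to cover the maximum `last_study_day`.
#' @param n_weeks Number of study weeks; required when `patients` is `NULL`.
#' @param week_length Days per week, default 7.
#' @return An object of class `study_week_grid`.
#' @export
study_week_grid <- function(patients = NULL, n_weeks = NULL, week_length = 7L) {
  week_length <- as_integerish(week_length)
  if (is.na(week_length) || week_length < 1L) {
    config_error("week_length must be an integer >= 1")
  }
  if (is.null(n_weeks)) {
    if (is.null(patients)) {
      config_error("either patients or n_weeks must be supplied")
    }
    patients <- patient_records(patients)
    n_weeks <- ceiling(max(patients$last_study_day) / week_length)
  }
  n_weeks <- as_integerish(n_weeks)
  if (is.na(n_weeks) || n_weeks < 1L) {
    config_error("n_weeks must be an integer >= 1")
  }
  structure(
    list(week_length = week_length, n_weeks = as.integer(n_weeks)),
    class = "study_week_grid"
  )
}

#' @export
print.study_week_grid <- function(x, ...) {
  cat(sprintf(
    "<study_week_grid> %d weeks of %d days (days 1..%d)\n",
    x$n_weeks, x$week_length, x$n_weeks * x$week_length
  ))
  invisible(x)
}

#' First and last study day of a week
#'
#' @param grid A [study_week_grid()].
#' @param week Week index (1-based), vectorized.
#' @return A tibble with columns `week`, `first_day`, `last_day`.
#' @export
week_bounds <- function(grid, week) {
  stopifnot(inherits(grid, "study_week_grid"))
  week <- as.integer(week)
  tibble::tibble(
    week = week,
    first_day = (week - 1L) * grid$week_length + 1L,
    last_day = week * grid$week_length
  )
}
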