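# Burden engine: interval -> week projection, per-patient weekly burden,
# risk sets, arm-level normalized series, cumulative AUC.
#
# The weekly burden score for a patient is
#   sum over distinct terms active that week of weight(term) * max grade,
# i.e. the grade-times-presence sum, with the highest severity used when the
# same term is reported at several grades within one week.

#' Weeks covered by an adverse-event interval
#'
#' A week is covered if the inclusive day interval `[start_day, end_day]`
#' intersects the week's day range: activity on any single day of a week
#' counts for the full week (the weekly estimate has no sub-week resolution).
#'
#' @param start_day,end_day Inclusive study-day interval (scalars).
#' @param grid A [study_week_grid()].
#' @return Integer vector of covered week indices (capped at `grid$n_weeks`).
#' @examples
#' g <- study_week_grid(n_weeks = 10)
#' weeks_covered(5, 9, g) # weeks 1 and 2
#' @export
weeks_covered <- function(start_day, end_day, grid) {
  stopifnot(inherits(grid, "study_week_grid"))
  if (is.na(end_day)) {
    validation_error("episode has no concrete end_day; run impute_end_dates() first")
  }
  stopifnot(length(start_day) == 1L, length(end_day) == 1L,
            start_day >= 1L, end_day >= start_day)
  L <- grid$week_length
  w1 <- (as.integer(start_day) - 1L) %/% L + 1L
  w2 <- min((as.integer(end_day) - 1L) %/% L + 1L, grid$n_weeks)
  if (w1 > w2) return(integer(0))
  seq.int(w1, w2)
}

#' Effective grade of a term within a week
#'
#' When the same TEAE term is reported at varying severity within one week,
#' the highest severity is used.
#'
#' @param grades Non-empty integer vector of grades 1-5.
#' @return The maximum grade, an integer.
#' @export
effective_grade <- function(grades) {
  if (length(grades) == 0) {
    validation_error("effective_grade() requires at least one grade")
  }
  grades <- as_integerish(grades)
  if (anyNA(grades) || any(grades < 1L | grades > 5L)) {
    validation_error("grades must be integers in 1..5")
  }
  max(grades)
}

# Weight lookup: `weights` is a named numeric vector (term -> weight > 0) or
# NULL for unit weights. Terms absent from the map get weight 1.
weight_map <- function(weights) {
  if (is.null(weights)) return(NULL)
  weights <- unlist(weights)
  w <- as.numeric(weights)
  names(w) <- normalize_term(names(weights))
  if (is.null(names(weights)) || anyNA(w) || any(w <= 0)) {
    config_error("weights must be a named vector of positive numbers")
  }
  w
}

weight_for <- function(terms, weights) {
  if (is.null(weights)) return(rep(1, length(terms)))
  out <- unname(weights[terms])
  out[is.na(out)] <- 1
  out
}

# Long table of effective grades: one row per (patient, term, week) with the
# week's max grade for that term. Episodes must have concrete end days.
term_week_grades <- function(episodes, grid, term_filter = NULL) {
  episodes <- ae_episodes(episodes)
  if (anyNA(episodes$end_day)) {
    validation_error("episodes contain missing end_day; run impute_end_dates() first")
  }
  if (!is.null(term_filter)) {
    episodes <- episodes[episodes$term %in% normalize_term(term_filter), ,
                         drop = FALSE]
  }
  L <- grid$week_length
  if (nrow(episodes) == 0) {
    return(tibble::tibble(
      patient_id = character(), term = character(),
      week = integer(), grade = integer()
    ))
  }
  w1 <- (episodes$start_day - 1L) %/% L + 1L
  w2 <- pmin((episodes$end_day - 1L) %/% L + 1L, grid$n_weeks)
  keep <- w1 <= w2
  w1 <- w1[keep]; w2 <- w2[keep]
  episodes <- episodes[keep, , drop = FALSE]
  n <- w2 - w1 + 1L
  idx <- rep.int(seq_len(nrow(episodes)), n)
  long <- tibble::tibble(
    patient_id = episodes$patient_id[idx],
    term = episodes$term[idx],
    week = sequence(n, from = w1),
    grade = episodes$grade[idx]
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$patient_id, .data$term, .data$week),
    grade = max(.data$grade), .groups = "drop"
  )
}

#' Per-patient weekly burden scores
#'
#' Computes the burden score for every (patient, week) cell: the sum over
#' distinct terms active in that week of `weight(term) * max grade`. Patients
#' and weeks with no active episodes score 0; only at-risk patient-weeks are
#' returned.
#'
#' @param episodes Episode table with concrete end days
#'   (see [impute_end_dates()]).
#' @param patients Patient table.
#' @param grid A [study_week_grid()]; defaults to the grid covering the
#'   maximum last study day.
#' @param weights Optional named vector of positive per-term weights
#'   (clinical-relevance weighting); unlisted terms get weight 1.
#' @param term_filter Optional character vector of terms; episodes of other
#'   terms contribute 0.
#' @return A tibble with columns `patient_id`, `arm`, `week`, `burden`,
#'   dense over all at-risk patient-weeks.
#' @export
burden_matrix <- function(episodes, patients, grid = NULL, weights = NULL,
                          term_filter = NULL) {
  patients <- patient_records(patients)
  if (is.null(grid)) grid <- study_week_grid(patients)
  weights <- weight_map(weights)
  unknown <- setdiff(ae_episodes(episodes)$patient_id, patients$patient_id)
  if (length(unknown) > 0) {
    validation_error(sprintf(
      "episode(s) reference unknown patient_id(s): %s",
      paste(head(unknown, 5L), collapse = ", ")
    ))
  }
  tw <- term_week_grades(episodes, grid, term_filter)
  tw$contribution <- weight_for(tw$term, weights) * tw$grade
  scores <- dplyr::summarise(
    dplyr::group_by(tw, .data$patient_id, .data$week),
    burden = sum(.data$contribution), .groups = "drop"
  )
  # dense grid over at-risk patient-weeks
  full <- tidyr::expand_grid(
    patient_id = patients$patient_id,
    week = seq_len(grid$n_weeks)
  )
  last <- patients$last_study_day[match(full$patient_id, patients$patient_id)]
  full <- full[last >= (full$week - 1L) * grid$week_length + 1L, , drop = FALSE]
  out <- dplyr::left_join(full, scores, by = c("patient_id", "week"))
  out$burden[is.na(out$burden)] <- 0
  out$arm <- patients$arm[match(out$patient_id, patients$patient_id)]
  out[, c("patient_id", "arm", "week", "burden")]
}

#' Burden score of one patient in one week
#'
#' Convenience scalar form of [burden_matrix()].
#'
#' @param patient_id Patient identifier.
#' @param week Week index (1-based).
#' @inheritParams burden_matrix
#' @return A single non-negative number.
#' @examples
#' # a grade-2 and a grade-1 TEAE active in the same week score 2 + 1 = 3
#' pats <- data.frame(patient_id = "P01", arm = "A", last_study_day = 28)
#' eps <- data.frame(
#'   patient_id = "P01", term = c("diarrhea", "skin rash"),
#'   grade = c(2, 1), start_day = c(8, 9), end_day = c(12, 13)
#' )
#' patient_week_burden("P01", 2, eps, pats)
#' @export
patient_week_burden <- function(patient_id, week, episodes, patients,
                                grid = NULL, weights = NULL,
                                term_filter = NULL) {
  bm <- burden_matrix(episodes, patients, grid, weights, term_filter)
  hit <- bm$burden[bm$patient_id == patient_id & bm$week == week]
  if (length(hit) == 0) return(0)
  hit
}

#' Is a patient at risk in a given week?
#'
#' A patient is at risk in week `w` if they are on study for at least one day
#' of that week, i.e. `last_study_day >= (w-1)*L + 1`. The alternative
#' (full-week residence) would discard every patient's final partial week.
#'
#' @param last_study_day Integer vector of last study days.
#' @param week Week index (scalar or vector, recycled).
#' @param grid A [study_week_grid()].
#' @return Logical vector.
#' @export
at_risk <- function(last_study_day, week, grid) {
  stopifnot(inherits(grid, "study_week_grid"))
  as.integer(last_study_day) >= (as.integer(week) - 1L) * grid$week_length + 1L
}

#' Weekly burden series for one treatment arm
#'
#' For every study week: the total burden summed over the arm's at-risk
#' patients, the risk-set size, the risk-set-normalized burden
#' (`total / n_at_risk`, 0 when the risk set is empty), and the
#' decomposition of the total by effective grade (for the stacked chart).
#'
#' @param arm Arm label; must appear in `patients$arm`.
#' @inheritParams burden_matrix
#' @param min_risk_set Optional minimum risk-set size; weeks with fewer
#'   at-risk patients are dropped from the series (the weekly estimate grows
#'   unstable as the denominator shrinks late in a trial). Default 0 keeps
#'   all weeks.
#' @return A tibble of class `arm_burden_series` with columns `week`,
#'   `total_burden`, `n_at_risk`, `normalized_burden`, `empty`,
#'   `grade_1` .. `grade_5`.
#' @export
arm_series <- function(arm, patients, episodes, grid = NULL, weights = NULL,
                       term_filter = NULL, min_risk_set = 0L) {
  patients <- patient_records(patients)
  if (!arm %in% patients$arm) {
    validation_error(sprintf(
      "unknown arm '%s'; arms present: %s",
      arm, paste(sort(unique(patients$arm)), collapse = ", ")
    ))
  }
  if (is.null(grid)) grid <- study_week_grid(patients)
  weights <- weight_map(weights)
  pats <- patients[patients$arm == arm, , drop = FALSE]
  eps <- ae_episodes(episodes)
  eps <- eps[eps$patient_id %in% pats$patient_id, , drop = FALSE]

  weeks <- seq_len(grid$n_weeks)
  n_at_risk <- vapply(
    weeks,
    function(w) sum(at_risk(pats$last_study_day, w, grid)),
    integer(1)
  )

  tw <- term_week_grades(eps, grid, term_filter)
  tw$contribution <- weight_for(tw$term, weights) * tw$grade
  by_grade <- dplyr::summarise(
    dplyr::group_by(tw, .data$week, .data$grade),
    burden = sum(.data$contribution), .groups = "drop"
  )
  grade_cols <- matrix(0, nrow = grid$n_weeks, ncol = 5L,
                       dimnames = list(NULL, paste0("grade_", 1:5)))
  if (nrow(by_grade) > 0) {
    grade_cols[cbind(by_grade$week, by_grade$grade)] <- by_grade$burden
  }
  total <- rowSums(grade_cols)

  out <- tibble::tibble(
    week = weeks,
    total_burden = total,
    n_at_risk = n_at_risk,
    normalized_burden = ifelse(n_at_risk > 0, total / n_at_risk, 0),
    empty = n_at_risk == 0L
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(grade_cols))
  if (min_risk_set > 0) {
    out <- out[out$n_at_risk >= min_risk_set, , drop = FALSE]
  }
  structure(out,
    class = c("arm_burden_series", class(out)),
    arm = arm, week_length = grid$week_length
  )
}

#' @export
print.arm_burden_series <- function(x, ...) {
  cat(sprintf(
    "<arm_burden_series> arm '%s', %d week(s), cumulative AUC %.4g\n",
    attr(x, "arm"), nrow(x), sum(x$normalized_burden)
  ))
  NextMethod()
}

#' Cumulative burden AUC of an arm series
#'
#' The area under the weekly burden curve by the rectangular (sum-of-bars)
#' rule, in units of burden-weeks: the AUC equals the sum of the bars shown
#' on the chart. It is the total accumulated burden over time and the
#' statistic compared between arms.
#'
#' @param series An [arm_series()] result (or any data frame with the chosen
#'   statistic column).
#' @param statistic `"normalized"` (risk-set-normalized, the default) or
#'   `"total"`.
#' @return A non-negative number.
#' @export
cumulative_auc <- function(series, statistic = c("normalized", "total")) {
  statistic <- match.arg(statistic)
  if (nrow(series) == 0) {
    validation_error("series is empty; cannot compute an AUC")
  }
  col <- if (statistic == "normalized") "normalized_burden" else "total_burden"
  sum(series[[col]])
}

#' Per-patient cumulative burden
#'
#' The sum of a patient's weekly burden scores over their at-risk weeks
#' (a per-patient AUC, used e.g. by the rank-based sensitivity test).
#'
#' @inheritParams burden_matrix
#' @return A tibble with columns `patient_id`, `arm`, `auc`, one row per
#'   patient (0 for AE-free patients).
#' @export
per_patient_auc <- function(episodes, patients, grid = NULL, weights = NULL,
                            term_filter = NULL) {
  patients <- patient_records(patients)
  bm <- burden_matrix(episodes, patients, grid, weights, term_filter)
  out <- dplyr::summarise(
    dplyr::group_by(bm, .data$patient_id, .data$arm),
    auc = sum(.data$burden), .groups = "drop"
  )
  out[match(patients$patient_id, out$patient_id), , drop = FALSE]
}

#' Tidy long-format export of arm burden series
#'
#' Binds one series per arm into a single long table suitable for CSV export.
#'
#' @param ... One or more [arm_series()] objects.
#' @return A tibble with an `arm` column followed by the series columns.
#' @export
bind_arm_series <- function(...) {
  series <- list(...)
  dplyr::bind_rows(lapply(series, function(s) {
    tibble::as_tibble(cbind(arm = attr(s, "arm"), as.data.frame(s)))
  }))
}
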