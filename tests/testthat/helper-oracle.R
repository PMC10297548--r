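# Independent brute-force oracle for the burden engine.
#
# Works at day resolution: every episode is expanded to its individual study
# days, the per-day per-term maximum grade is taken, days are collapsed to
# weeks by per-term maximum, and weighted grades are summed. Deliberately
# shares no code with the package's interval arithmetic.

# Dense per-patient-week burden table over at-risk weeks.
oracle_burden_matrix <- function(episodes, patients, week_length = 7,
                                 weights = NULL, term_filter = NULL) {
  n_weeks <- ceiling(max(patients$last_study_day) / week_length)
  horizon <- n_weeks * week_length
  rows <- list()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    last <- patients$last_study_day[i]
    eps <- episodes[episodes$patient_id == pid, , drop = FALSE]
    if (!is.null(term_filter)) {
      eps <- eps[eps$term %in% term_filter, , drop = FALSE]
    }
    # day-level grade profile per term
    profiles <- list()
    for (j in seq_len(nrow(eps))) {
      tm <- eps$term[j]
      if (is.null(profiles[[tm]])) profiles[[tm]] <- integer(horizon)
      days <- seq(eps$start_day[j], min(eps$end_day[j], horizon))
      profiles[[tm]][days] <- pmax(profiles[[tm]][days], eps$grade[j])
    }
    for (w in seq_len(n_weeks)) {
      if (last < (w - 1) * week_length + 1) next
      days <- ((w - 1) * week_length + 1):(w * week_length)
      burden <- 0
      for (tm in names(profiles)) {
        gmax <- max(profiles[[tm]][days])
        if (gmax > 0) {
          wt <- if (!is.null(weights) && tm %in% names(weights)) {
            unname(weights[[tm]])
          } else 1
          burden <- burden + wt * gmax
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, week = w, burden = burden,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$patient_id, out$week), , drop = FALSE]
}

# Arm-level normalized weekly series and AUC from the day-level oracle.
oracle_arm_auc <- function(arm, episodes, patients, week_length = 7,
                           weights = NULL, term_filter = NULL) {
  pats <- patients[patients$arm == arm, , drop = FALSE]
  eps <- episodes[episodes$patient_id %in% pats$patient_id, , drop = FALSE]
  bm <- oracle_burden_matrix(eps, pats, week_length, weights, term_filter)
  n_weeks <- ceiling(max(patients$last_study_day) / week_length)
  auc <- 0
  for (w in seq_len(n_weeks)) {
    at_risk <- sum(pats$last_study_day >= (w - 1) * week_length + 1)
    if (at_risk == 0) next
    auc <- auc + sum(bm$burden[bm$week == w]) / at_risk
  }
  auc
}
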