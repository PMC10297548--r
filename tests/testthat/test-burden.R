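# Burden engine: interval-to-week projection, weekly scores, risk sets,
# arm series, AUC. Expected values for the interval examples were frozen
# from the day-enumeration oracle in helper-oracle.R.

test_that("interval-to-week projection matches day enumeration", {
  g <- study_week_grid(n_weeks = 10)
  expect_equal(weeks_covered(5, 9, g), c(1L, 2L))
  expect_equal(weeks_covered(8, 8, g), 2L)
  expect_equal(weeks_covered(1, 7, g), 1L)
  # property: w covered iff some day of [start, end] falls in the week
  set.seed(11)
  for (i in 1:50) {
    s <- sample(1:70, 1)
    e <- s + sample(0:30, 1)
    got <- weeks_covered(s, e, g)
    for (w in 1:10) {
      days <- ((w - 1) * 7 + 1):(w * 7)
      expect_equal(w %in% got, any(days >= s & days <= e))
    }
  }
  expect_error(weeks_covered(5, NA, g), class = "aeburden_validation_error")
})

test_that("the highest severity is used when a term repeats within a week", {
  expect_equal(effective_grade(c(1, 3)), 3)
  expect_equal(effective_grade(2), 2)
  expect_equal(effective_grade(c(2, 2, 2)), 2)
  expect_error(effective_grade(integer(0)), class = "aeburden_validation_error")
  expect_error(effective_grade(c(1, 6)), class = "aeburden_validation_error")
})

test_that("weekly burden is the grade-times-presence sum over distinct terms", {
  pats <- data.frame(patient_id = "P01", arm = "A", last_study_day = 28)
  # grade-2 diarrhea and grade-1 skin rash in the same week: 2 + 1 = 3
  eps <- data.frame(
    patient_id = "P01", term = c("diarrhea", "skin rash"),
    grade = c(2, 1), start_day = c(8, 9), end_day = c(12, 13)
  )
  expect_equal(patient_week_burden("P01", 2, eps, pats), 3)
  # no active episodes -> 0
  expect_equal(patient_week_burden("P01", 4, eps, pats), 0)
  # same term twice (grades 1 and 3 -> 3) plus grade-2 neutropenia -> 5
  eps2 <- data.frame(
    patient_id = "P01",
    term = c("diarrhea", "diarrhea", "neutropenia"),
    grade = c(1, 3, 2), start_day = c(8, 10, 9), end_day = c(9, 12, 11)
  )
  expect_equal(patient_week_burden("P01", 2, eps2, pats), 5)
  expect_equal(
    oracle_burden_matrix(eps2, pats)$burden[2], 5
  ) # oracle agrees
  # per-term weights scale the contributions
  expect_equal(
    patient_week_burden("P01", 2, eps2, pats,
                        weights = c(diarrhea = 2, neutropenia = 0.5)),
    3 * 2 + 2 * 0.5
  )
})

test_that("a patient is at risk in any week overlapping their on-study time", {
  g <- study_week_grid(n_weeks = 10)
  expect_true(at_risk(52, 8, g))   # week 8 covers days 50..56
  expect_false(at_risk(52, 9, g))  # week 9 starts on day 57
  expect_true(at_risk(7, 1, g))
  expect_false(at_risk(7, 2, g))
})

test_that("arm series totals, normalization and degenerate weeks", {
  pats <- data.frame(
    patient_id = c("P1", "P2"), arm = "A", last_study_day = c(7, 7)
  )
  eps <- data.frame(
    patient_id = c("P1", "P1", "P2"),
    term = c("diarrhea", "rash", "rash"),
    grade = c(2, 1, 1), start_day = c(1, 2, 3), end_day = c(5, 6, 4)
  )
  g <- study_week_grid(n_weeks = 2)
  s <- arm_series("A", pats, eps, g)
  expect_equal(s$total_burden, c(4, 0))
  expect_equal(s$n_at_risk, c(2L, 0L))
  expect_equal(s$normalized_burden, c(2, 0))
  expect_equal(s$empty, c(FALSE, TRUE))
  # grade decomposition sums to the total
  expect_equal(rowSums(s[, paste0("grade_", 1:5)]), s$total_burden)
  expect_equal(unname(unlist(s[1, c("grade_1", "grade_2")])), c(2, 2))
  # single patient with the two-TEAE week normalizes to 3
  s1 <- arm_series("A", pats[1, ], eps[eps$patient_id == "P1", ], g)
  expect_equal(s1$normalized_burden[1], 3)
  expect_error(arm_series("Z", pats, eps, g),
               class = "aeburden_validation_error", regexp = "Z")
})

test_that("cumulative AUC is the sum of the plotted bars", {
  s <- tibble::tibble(normalized_burden = c(1, 0.5, 0.25),
                      total_burden = c(2, 1, 1))
  expect_equal(cumulative_auc(s), 1.75)
  expect_equal(cumulative_auc(s, "total"), 4)
  expect_equal(cumulative_auc(tibble::tibble(normalized_burden = c(0, 0))), 0)
  expect_error(cumulative_auc(s[0, ]), class = "aeburden_validation_error")
})

test_that("per-patient cumulative burden matches the day-level oracle", {
  pats <- data.frame(patient_id = c("P1", "P2"), arm = "A",
                     last_study_day = c(28, 28))
  eps <- data.frame(
    patient_id = "P1", term = c("diarrhea", "skin rash"),
    grade = c(2, 1), start_day = c(8, 9), end_day = c(12, 13)
  )
  pa <- per_patient_auc(eps, pats)
  expect_equal(pa$auc[pa$patient_id == "P1"], 3)
  expect_equal(pa$auc[pa$patient_id == "P2"], 0) # AE-free patient
  sim <- random_study(7)
  got <- per_patient_auc(sim$episodes, sim$patients)
  ora <- oracle_burden_matrix(sim$episodes, sim$patients)
  ora_auc <- tapply(ora$burden, ora$patient_id, sum)
  expect_equal(got$auc, as.numeric(ora_auc[got$patient_id]))
})

test_that("burden matrix equals the brute-force day-level oracle", {
  for (seed in c(3, 14, 59)) {
    sim <- random_study(seed)
    got <- burden_matrix(sim$episodes, sim$patients)
    got <- got[order(got$patient_id, got$week), ]
    ora <- oracle_burden_matrix(sim$episodes, sim$patients)
    expect_equal(got$burden, ora$burden)
    expect_equal(got$patient_id, ora$patient_id)
    expect_equal(got$week, ora$week)
  }
})

test_that("burden is monotone in episodes and grades", {
  sim <- random_study(21)
  bm0 <- burden_matrix(sim$episodes, sim$patients)
  # adding an episode never decreases any cell
  extra <- sim$episodes[1, ]
  extra$term <- "extra term"
  bm1 <- burden_matrix(rbind(sim$episodes, extra), sim$patients)
  expect_true(all(bm1$burden >= bm0$burden))
  # raising a grade never decreases any cell
  eps2 <- sim$episodes
  eps2$grade <- pmin(eps2$grade + 1L, 5L)
  bm2 <- burden_matrix(eps2, sim$patients)
  expect_true(all(bm2$burden >= bm0$burden))
})

test_that("term filtering is additive and consistent", {
  sim <- random_study(33)
  terms <- sort(unique(sim$episodes$term))
  bm_all <- burden_matrix(sim$episodes, sim$patients)
  # filtering to the full term set reproduces the unfiltered result
  bm_filt <- burden_matrix(sim$episodes, sim$patients, term_filter = terms)
  expect_equal(bm_filt, bm_all)
  # with unit weights the per-term burdens sum to the overall burden
  per_term <- lapply(terms, function(tm) {
    burden_matrix(sim$episodes, sim$patients, term_filter = tm)$burden
  })
  expect_equal(Reduce(`+`, per_term), bm_all$burden)
})

test_that("normalized burden respects its upper bound", {
  sim <- random_study(8)
  g <- study_week_grid(sim$patients)
  n_terms <- length(unique(sim$episodes$term))
  for (arm in c("A", "B")) {
    s <- arm_series(arm, sim$patients, sim$episodes, g)
    expect_true(all(s$normalized_burden >= 0))
    expect_true(all(s$normalized_burden <= 5 * n_terms))
  }
})

test_that("arm AUC is reconstructed from per-patient weekly burdens", {
  sim <- random_study(77)
  g <- study_week_grid(sim$patients)
  bm <- burden_matrix(sim$episodes, sim$patients, g)
  for (arm in c("A", "B")) {
    s <- arm_series(arm, sim$patients, sim$episodes, g)
    arm_bm <- bm[bm$arm == arm, ]
    weekly <- tapply(arm_bm$burden, arm_bm$week, sum)
    n_risk <- tapply(arm_bm$burden, arm_bm$week, length)
    expect_equal(cumulative_auc(s), sum(weekly / n_risk))
    expect_equal(cumulative_auc(s), oracle_arm_auc(arm, sim$episodes, sim$patients))
  }
})
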