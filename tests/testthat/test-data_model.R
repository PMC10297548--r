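# Readers, validation, end-date imputation, and the study-week grid.

test_that("episode construction maps and normalizes fields", {
  eps <- ae_episodes(data.frame(
    patient_id = "P01", term = "  Diarrhea ", grade = "2",
    start_day = 8, end_day = 21
  ))
  expect_equal(eps$patient_id, "P01")
  expect_equal(eps$term, "diarrhea")
  expect_identical(eps$grade, 2L)
  expect_identical(eps$start_day, 8L)
  expect_identical(eps$end_day, 21L)
  expect_false(eps$ongoing)

  # blank end day plus ongoing flag
  eps <- ae_episodes(data.frame(
    patient_id = "P02", term = "rash", grade = 1,
    start_day = 3, end_day = NA, ongoing = TRUE
  ))
  expect_true(eps$ongoing)
  expect_true(is.na(eps$end_day))
})

test_that("episode invariants are enforced with row references", {
  base <- data.frame(
    patient_id = c("P1", "P2"), term = c("a", "b"),
    grade = c(2, 6), start_day = c(1, 1), end_day = c(5, 5)
  )
  expect_error(ae_episodes(base), class = "aeburden_validation_error",
               regexp = "row.*2")
  base$grade <- c(2, "x")
  expect_error(ae_episodes(base), class = "aeburden_validation_error")
  base$grade <- c(2, NA)
  expect_error(ae_episodes(base), class = "aeburden_validation_error")
  base$grade <- c(2, 3)
  base$start_day <- c(0, 1)
  expect_error(ae_episodes(base), class = "aeburden_validation_error",
               regexp = "start_day")
  base$start_day <- c(10, 1)
  base$end_day <- c(5, 5)
  expect_error(ae_episodes(base), class = "aeburden_validation_error",
               regexp = "end_day")
  base$end_day <- c(12, 5)
  base$term <- c("a", "   ")
  expect_error(ae_episodes(base), class = "aeburden_validation_error",
               regexp = "term")
})

test_that("missing mapped columns raise a configuration error naming them", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    data.frame(USUBJID = "P1", AEDECOD = "Rash", AETOXGR = 1, AESTDY = 2),
    path
  )
  expect_error(
    read_ae_table(path),
    class = "aeburden_config_error", regexp = "patient_id"
  )
  # CDISC-style headers map via the column map without editing the file
  eps <- read_ae_table(path, column_map = c(
    patient_id = "USUBJID", term = "AEDECOD",
    grade = "AETOXGR", start_day = "AESTDY"
  ))
  expect_equal(eps$term, "rash")
  expect_true(eps$ongoing) # no end column -> ongoing
})

test_that("patient table validation: duplicates, arm count", {
  path <- withr::local_tempfile(fileext = ".csv")
  pats <- data.frame(
    patient_id = c("P1", "P2", "P3"), arm = c("A", "A", "B"),
    last_study_day = c(10, 20, 30)
  )
  readr::write_csv(pats, path)
  got <- read_patient_table(path)
  expect_equal(nrow(got), 3)

  readr::write_csv(rbind(pats, pats[1, ]), path)
  expect_error(read_patient_table(path),
               class = "aeburden_validation_error", regexp = "P1")

  pats$arm <- c("A", "B", "C")
  readr::write_csv(pats, path)
  expect_error(read_patient_table(path),
               class = "aeburden_validation_error", regexp = "A, B, C")
})

test_that("canonical dialect round-trips exactly, including ongoing flags", {
  eps <- ae_episodes(data.frame(
    patient_id = c("P1", "P1", "P2"),
    term = c("diarrhea", "skin rash", "neutropenia"),
    grade = c(2L, 1L, 4L),
    start_day = c(8L, 9L, 15L),
    end_day = c(21L, NA, 30L),
    ongoing = c(FALSE, TRUE, FALSE)
  ))
  pats <- patient_records(data.frame(
    patient_id = c("P1", "P2"), arm = c("A", "B"),
    last_study_day = c(52L, 40L)
  ))
  ae_path <- withr::local_tempfile(fileext = ".csv")
  pt_path <- withr::local_tempfile(fileext = ".csv")
  write_ae_table(eps, ae_path)
  write_patient_table(pats, pt_path)
  expect_identical(read_ae_table(ae_path), eps)
  expect_identical(read_patient_table(pt_path), pats)
})

test_that("end-date imputation follows the last-study-day rule", {
  pats <- data.frame(patient_id = "P1", arm = "A", last_study_day = 52)
  # ongoing episode ends on the patient's last study day
  eps <- data.frame(patient_id = "P1", term = "rash", grade = 1,
                    start_day = 30, end_day = NA, ongoing = TRUE)
  expect_equal(impute_end_dates(eps, pats)$end_day, 52L)
  # closed episodes are unchanged
  eps <- data.frame(patient_id = "P1", term = "rash", grade = 1,
                    start_day = 8, end_day = 21)
  expect_equal(impute_end_dates(eps, pats)$end_day, 21L)
  # episodes running past the last study day are truncated to it
  eps$end_day <- 60
  expect_equal(impute_end_dates(eps, pats)$end_day, 52L)
  # unknown patient and start-after-last-day are rejected
  eps$patient_id <- "P9"
  expect_error(impute_end_dates(eps, pats),
               class = "aeburden_validation_error", regexp = "P9")
  eps <- data.frame(patient_id = "P1", term = "rash", grade = 1,
                    start_day = 60, end_day = NA, ongoing = TRUE)
  expect_error(impute_end_dates(eps, pats),
               class = "aeburden_validation_error")
})

test_that("no episode extends past its patient's last study day after imputation", {
  sim <- random_study(42)
  last <- sim$patients$last_study_day[
    match(sim$episodes$patient_id, sim$patients$patient_id)
  ]
  expect_true(all(sim$episodes$end_day <= last))
  expect_true(all(!is.na(sim$episodes$end_day)))
})

test_that("study-week grid covers the maximum last study day", {
  pats <- data.frame(patient_id = c("P1", "P2"), arm = c("A", "B"),
                     last_study_day = c(52, 15))
  g <- study_week_grid(pats)
  expect_equal(g$n_weeks, 8) # ceiling(52 / 7)
  expect_equal(week_bounds(g, 8)$first_day, 50)
  expect_equal(week_bounds(g, 8)$last_day, 56)
  g3 <- study_week_grid(n_weeks = 4, week_length = 14)
  expect_equal(week_bounds(g3, 2)$first_day, 15)
  expect_error(study_week_grid(), class = "aeburden_config_error")
})
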