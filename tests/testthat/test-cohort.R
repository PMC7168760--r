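## Ten hand-built patients, each violating exactly one selection criterion
## (in the study's order), plus one survivor: the flow chart must drop one
## patient per step. Enumerated by hand before implementation.
ten_patient_db <- function() {
  pats <- rbind(
    patient_row(1),                                   # survivor
    patient_row(2, birth_year = 1996),                # eligible (P10 stay)
    patient_row(3),                                   # washout violation
    patient_row(4),                                   # bad hospital category
    patient_row(5),                                   # zero duration
    patient_row(6, birth_year = 1996),                # minor (age 17)
    patient_row(7, enrollment_day = 200L),            # short history
    patient_row(8, death_day = 452L),                 # dies during stay
    patient_row(9, observation_end = 600L),           # short follow-up
    patient_row(10))                                  # rehab stay after
  pats$birth_year[pats$patient_id == 6] <- 1996L
  pats$birth_year[pats$patient_id == 2] <- 1950L
  stays <- rbind(
    stay_row(1, 1, 450, 455),
    stay_row(2, 2, 720, 736),                 # discharge beyond year end
    stay_row(3, 3, 368, 373),
    stay_row(4, 3, 345, 347),                 # prior ACS 23 days before (2012)
    stay_row(5, 4, 450, 455, category = "other"),
    stay_row(6, 5, 450, 450),                 # duration zero
    stay_row(7, 6, 450, 455),
    stay_row(8, 7, 450, 455),
    stay_row(9, 8, 450, 455),                 # death_day 452 < discharge
    stay_row(10, 9, 450, 455),
    stay_row(11, 10, 450, 455),
    stay_row(12, 10, 470, 490, primary = "Z50.1", category = "rehab"))
  make_claims_db(patients = pats, hospital_stays = stays)
}

test_that("each selection criterion excludes exactly its designated patient", {
  db <- ten_patient_db()
  res <- select_cohort(db)
  expect_equal(res$flowchart$n_remaining, c(10:1))
  expect_equal(res$cohort$patient_id, 1L)
  expect_equal(res$cohort$index_date, 455L)
  expect_equal(res$cohort$stratum, "NSTEMI")
  expect_equal(res$cohort$index_stay_duration, 5L)
})

test_that("zero-duration stays and in-hospital deaths are excluded", {
  db <- ten_patient_db()
  res <- select_cohort(db)
  fc <- res$flowchart
  dur_row <- grep("duration", fc$criterion)
  expect_equal(fc$n_remaining[dur_row - 1L] - fc$n_remaining[dur_row], 1L)
  alive_row <- grep("alive", fc$criterion)
  expect_equal(fc$n_remaining[alive_row - 1L] -
                 fc$n_remaining[alive_row], 1L)
})

test_that("an empty database yields an empty cohort and an all-zero flow chart", {
  res <- select_cohort(make_claims_db())
  expect_equal(nrow(res$cohort), 0L)
  expect_true(all(res$flowchart$n_remaining == 0L))
})

test_that("flow-chart accounting is exact and selection is idempotent", {
  db <- simulate_claims(simulation_config(n_patients = 800, seed = 3))
  res <- select_cohort(db)
  fc <- res$flowchart
  expect_false(is.unsorted(rev(fc$n_remaining)))
  drops <- -diff(fc$n_remaining)
  expect_equal(fc$n_remaining[1] - sum(drops),
               fc$n_remaining[nrow(fc)])
  expect_equal(nrow(res$cohort), fc$n_remaining[nrow(fc)])

  ## rerun on the selected subset: nothing changes
  keep <- res$cohort$patient_id
  db2 <- db
  db2$patients <- db$patients[patient_id %in% keep]
  for (tb in c("dispensings", "hospital_stays", "stay_diagnoses",
               "stay_procedures", "ltd_registrations", "visits",
               "lab_claims")) {
    db2[[tb]] <- db[[tb]][patient_id %in% keep]
  }
  res2 <- select_cohort(db2)
  expect_equal(res2$cohort$patient_id, res$cohort$patient_id)
  expect_equal(res2$cohort$index_date, res$cohort$index_date)
  ## every cohort member: history before index and follow-up (or death)
  co <- merge(res$cohort, db$patients[, .(patient_id, enrollment_day)],
              by = "patient_id")
  expect_true(all(co$enrollment_day <= co$index_admission_day - 365))
  expect_true(all(!is.na(co$death_day) |
                    co$observation_end >= co$index_date + 365))
})

test_that("an ACS code without a stratum mapping is a configuration error", {
  db <- ten_patient_db()
  cr <- selection_criteria(acs_primary_codes = c(study_code_sets()$acs,
                                                 "I24.9"))
  db$hospital_stays[patient_id == 1, primary_code := "I24.9"]
  expect_error(select_cohort(db, cr), "stratum")
})
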