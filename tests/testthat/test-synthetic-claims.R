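test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(n_patients = 1), "n_patients")
  expect_error(simulation_config(baseline_hazards = c(acs = 0.07,
                                                      stroke = 0.015,
                                                      death = -0.1,
                                                      bleeding = 0.03)),
               "hazards")
  expect_error(simulation_config(code_vocab_sizes = c(diagnosis = 0,
                                                      drug = 10, lab = 10,
                                                      procedure = 10,
                                                      visit = 5, ltd = 5)),
               "vocabulary")
})

test_that("identical seeds give byte-identical databases", {
  cfg <- simulation_config(n_patients = 300, seed = 42)
  db1 <- simulate_claims(cfg)
  db2 <- simulate_claims(cfg)
  for (tb in c("patients", "dispensings", "hospital_stays",
               "stay_diagnoses", "stay_procedures", "ltd_registrations",
               "visits", "lab_claims")) {
    expect_identical(db1[[tb]], db2[[tb]], info = tb)
  }
  db3 <- simulate_claims(simulation_config(n_patients = 300, seed = 43))
  expect_false(identical(db1$dispensings, db3$dispensings))
})

test_that("database invariants hold on a simulated sample", {
  db <- simulate_claims(simulation_config(n_patients = 500, seed = 7))
  expect_silent(validate_claims_db(db))
  hs <- db$hospital_stays
  expect_true(all(hs$discharge_day >= hs$admission_day))
  ids <- db$patients$patient_id
  expect_true(all(db$dispensings$patient_id %in% ids))
  expect_true(all(db$stay_diagnoses$stay_id %in% hs$stay_id))
  ## every patient with an index stay has a year of record before it
  tr <- db$meta$truth[has_index == TRUE & fate != "short_history"]
  pat <- merge(tr, db$patients, by = "patient_id")
  expect_true(all(pat$enrollment_day <= pat$index_admission_day - 365))
})

test_that("null channeling balances latent states across arms", {
  zero <- c(intercept = 0, cardiometabolic = 0, frailty = 0, age = 0,
            female = 0, stemi = 0, nstemi = 0)
  cfg <- simulation_config(
    n_patients = 20000, seed = 11,
    channeling_coefficients = list(ticagrelor = zero, prasugrel = zero))
  db <- simulate_claims(cfg)
  tr <- db$meta$truth[treatment %in% c("ticagrelor", "clopidogrel")]
  for (lat in c("latent_cardiometabolic", "latent_frailty")) {
    gap <- abs(tr[treatment == "ticagrelor", mean(get(lat))] -
                 tr[treatment == "clopidogrel", mean(get(lat))])
    expect_lt(gap, 0.03)
  }
  ## channeling off: arm shares near 1/3 each among treated
  sh <- db$meta$truth[treatment != "none", table(treatment) /
                        sum(treatment != "none")]
  expect_true(all(abs(sh - 1 / 3) < 0.03))
})

test_that("event incidence recovers the baseline hazard without covariate effects", {
  null_hr <- list(
    clopidogrel = c(acs = 0, stroke = 0, death = 0, bleeding = 0),
    ticagrelor = c(acs = 0, stroke = 0, death = 0, bleeding = 0),
    prasugrel = c(acs = 0, stroke = 0, death = 0, bleeding = 0))
  null_coef <- list(
    acs = c(cardiometabolic = 0, frailty = 0, age = 0),
    stroke = c(cardiometabolic = 0, frailty = 0, age = 0),
    death = c(cardiometabolic = 0, frailty = 0, age = 0),
    bleeding = c(cardiometabolic = 0, frailty = 0, age = 0))
  cfg <- simulation_config(n_patients = 20000, seed = 12,
                           true_log_hazard_ratios = null_hr,
                           hazard_coefficients = null_coef)
  db <- simulate_claims(cfg)
  tr <- db$meta$truth[has_index == TRUE & fate != "death_in_stay"]
  pat <- merge(tr, db$patients[, .(patient_id, observation_end)],
               by = "patient_id")
  for (comp in c("death", "acs")) {
    ev_day <- pat[[paste0("event_", comp)]]
    t_raw <- ifelse(is.na(ev_day), Inf, ev_day - pat$index_discharge_day)
    ## censor death-competing components at death
    if (comp != "death") {
      t_death <- ifelse(is.na(pat$event_death), Inf,
                        pat$event_death - pat$index_discharge_day)
      cens <- pmin(365, t_death)
    } else {
      cens <- rep(365, nrow(pat))
    }
    ev <- as.integer(t_raw <= cens)
    t_obs <- pmin(t_raw, cens)
    lambda_hat <- sum(ev) / (sum(t_obs) / 365)
    lambda <- cfg$baseline_hazards[[comp]]
    rel_err <- abs(lambda_hat - lambda) / lambda
    expect_lt(rel_err, 3 / sqrt(sum(ev)))
  }
})

test_that("write/read round-trips a database exactly", {
  db <- simulate_claims(simulation_config(n_patients = 150, seed = 5))
  dir <- withr::local_tempdir()
  man <- write_claims_db(db, dir)
  back <- read_claims_db(dir)
  for (tb in c("patients", "dispensings", "hospital_stays",
               "stay_diagnoses", "stay_procedures", "ltd_registrations",
               "visits", "lab_claims")) {
    expect_equal(as.data.frame(db[[tb]]), as.data.frame(back[[tb]]),
                 info = tb)
    expect_identical(man$tables[[tb]]$rows, nrow(db[[tb]]))
  }
})

test_that("an empty database writes header-only tables with zero counts", {
  db <- make_claims_db()
  dir <- withr::local_tempdir()
  man <- write_claims_db(db, dir)
  expect_true(all(vapply(man$tables, function(x) x$rows,
                         numeric(1)) == 0))
  back <- read_claims_db(dir)
  expect_identical(nrow(back$patients), 0L)
})
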