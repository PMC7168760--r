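## a minimal exposed patient: index at 455, first dispensing at day 460,
## exposure to 455 + 365 unless stated otherwise
ep_row <- function(id, first = 460L, exp_end = 820L) {
  data.table(patient_id = as.integer(id), treatment = "ticagrelor",
             first_dispensing_day = as.integer(first),
             exposure_end_day = as.integer(exp_end))
}

test_that("event times honor exposure censoring and the composite rule", {
  db <- make_claims_db(
    patients = rbind(patient_row(1), patient_row(2), patient_row(3)),
    hospital_stays = rbind(
      stay_row(1, 1, 560, 565, primary = "I21.0"),   # ACS at day 100
      stay_row(2, 2, 550, 555, primary = "I21.0")))  # ACS after switch
  eps <- rbind(ep_row(1), ep_row(2, exp_end = 520L), ep_row(3))
  ev <- derive_event_times(db, eps,
                           endpoint_definitions()$primary_effectiveness)
  ev <- ev[order(patient_id)]
  ## patient 1: event at day 560, time from first dispensing (460)
  expect_equal(ev$event, c(1L, 0L, 0L))
  expect_equal(ev$time[1], 100)
  ## patient 2: switched at 520, ACS at 550 -> censored at exposure end
  expect_equal(ev$time[2], 60)
  ## patient 3: full exposure, eventless
  expect_equal(ev$time[3], 360)
})

test_that("death is a component of the effectiveness composite", {
  db <- make_claims_db(patients = rbind(
    patient_row(1, death_day = 700L), patient_row(2)))
  ev <- derive_event_times(db, rbind(ep_row(1, exp_end = 700L),
                                     ep_row(2)),
                           endpoint_definitions()$primary_effectiveness)
  expect_equal(ev[patient_id == 1, event], 1L)
  ## but not of the safety endpoint
  ev2 <- derive_event_times(db, rbind(ep_row(1, exp_end = 700L),
                                      ep_row(2)),
                            endpoint_definitions()$primary_safety)
  expect_equal(ev2[patient_id == 1, event], 0L)
})

test_that("incidence arithmetic and degenerate inputs", {
  r <- estimate_incidence(rep(365, 10), rep(0, 10))
  expect_equal(r$rate_per_100py, 0)
  expect_true(all(r$km$survival == 1))
  ## 2 events in 50 PY -> 4 per 100 PY
  r <- estimate_incidence(rep(365, 50), c(1, 1, rep(0, 48)))
  expect_equal(r$rate_per_100py, 4)
  expect_error(estimate_incidence(c(0, 10), c(0, 0)), "> 0")
})

test_that("KM equals empirical survival without censoring and the exponential closed form", {
  set.seed(15)
  ## no censoring: all subjects followed to the event
  t_ev <- sample(1:50, 30, replace = TRUE)
  r <- estimate_incidence(t_ev, rep(1, 30))
  for (k in seq_len(nrow(r$km))) {
    expect_equal(r$km$survival[k], mean(t_ev > r$km$time[k]),
                 tolerance = 1e-12)
  }
  ## exponential, lambda = 0.2 / year, censoring at 1 year, n = 5000
  n <- 5000
  t_true <- rexp(n, 0.2) * 365
  ev <- as.integer(t_true <= 365)
  tt <- pmin(t_true, 365)
  r <- estimate_incidence(tt, ev)
  s_hat <- min(r$km$survival)
  s_true <- exp(-0.2)
  se <- sqrt(s_true * (1 - s_true) / n)
  expect_lt(abs(s_hat - s_true), 3 * se)
})

test_that("person-time is conserved across arms", {
  set.seed(16)
  tt <- runif(500, 1, 365)
  ev <- rbinom(500, 1, 0.2)
  tr <- rep(c(TRUE, FALSE), 250)
  res <- compare_incidence(tt, ev, tr)
  expect_equal(res$arms$treated$person_years +
                 res$arms$comparator$person_years, sum(tt) / 365,
               tolerance = 1e-12)
})

test_that("the Poisson rate ratio equals the crude rate ratio without covariates", {
  set.seed(18)
  tt <- runif(200, 30, 365)
  ev <- rbinom(200, 1, 0.15)          # ~30 events: Poisson branch
  tr <- rep(c(TRUE, FALSE), 100)
  if (sum(ev) > 100) ev[ev == 1][1:(sum(ev) - 100)] <- 0
  res <- compare_incidence(tt, ev, tr)
  expect_true(res$model %in% c("poisson", "quasi_poisson"))
  crude_rr <- (sum(ev[tr]) / sum(tt[tr])) /
    (sum(ev[!tr]) / sum(tt[!tr]))
  expect_equal(res$estimate, crude_rr, tolerance = 1e-8)
})

test_that("the 100-event rule switches between Cox and Poisson", {
  set.seed(19)
  n <- 2000
  tt <- rep(300, n)
  tr <- rep(c(TRUE, FALSE), n / 2)
  ev <- c(rep(1, 40), rep(0, n - 40))          # 40 events
  res <- compare_incidence(tt, ev, tr)
  expect_true(res$model %in% c("poisson", "quasi_poisson"))
  ev <- c(rep(1, 150), rep(0, n - 150))        # 150 events
  tt2 <- c(runif(150, 10, 300), rep(300, n - 150))
  res <- compare_incidence(tt2, ev, tr)
  expect_equal(res$model, "cox")
  expect_true(res$ci[1] <= res$estimate && res$estimate <= res$ci[2])
})

test_that("identical arms give a null ratio with a covering CI", {
  set.seed(20)
  t1 <- runif(300, 10, 365)
  e1 <- rbinom(300, 1, 0.4)
  tt <- c(t1, t1); ev <- c(e1, e1)
  tr <- rep(c(TRUE, FALSE), each = 300)
  res <- compare_incidence(tt, ev, tr)
  expect_equal(res$estimate, 1, tolerance = 1e-6)
  expect_true(res$ci[1] <= 1 && 1 <= res$ci[2])
  expect_error(compare_incidence(tt, rep(0, 600), tr), "no events")
})

test_that("month-only death dates follow the day-15 rule", {
  ## month starting at day 600
  expect_equal(resolve_death_day(600L), 614L)
  ## hospitalization ending after the 15th in the same month overrides
  expect_equal(resolve_death_day(600L, stay_end_days = c(620L, 590L)),
               620L)
  ## hospitalization ending before the 15th does not
  expect_equal(resolve_death_day(600L, stay_end_days = 605L), 614L)
})
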