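library(data.table)

## ---- hand-built claims databases ---------------------------------------

empty_claims_tables <- function() {
  list(
    patients = data.table(
      patient_id = integer(), gender = character(),
      birth_year = integer(), cmu_c = logical(),
      enrollment_day = integer(), observation_end = integer(),
      death_day = integer()),
    dispensings = data.table(
      patient_id = integer(), day = integer(), code = character(),
      packs = integer(), units_per_pack = integer(),
      ddd_per_unit = numeric()),
    hospital_stays = data.table(
      stay_id = integer(), patient_id = integer(),
      admission_day = integer(), discharge_day = integer(),
      primary_code = character(), intensive_care = logical(),
      hospital_category = character()),
    stay_diagnoses = data.table(
      stay_id = integer(), patient_id = integer(), code = character(),
      type = character()),
    stay_procedures = data.table(
      stay_id = integer(), patient_id = integer(), code = character()),
    ltd_registrations = data.table(
      patient_id = integer(), code = character(), start_day = integer(),
      end_day = integer()),
    visits = data.table(
      patient_id = integer(), day = integer(), specialty = character()),
    lab_claims = data.table(
      patient_id = integer(), day = integer(), code = character()))
}

make_claims_db <- function(...) {
  db <- empty_claims_tables()
  over <- list(...)
  for (nm in names(over)) {
    db[[nm]] <- rbind(db[[nm]], as.data.table(over[[nm]]), fill = TRUE)
    for (j in names(db[[nm]])) {
      proto <- empty_claims_tables()[[nm]][[j]]
      if (is.integer(proto)) db[[nm]][[j]] <- as.integer(db[[nm]][[j]])
    }
  }
  db$meta <- list()
  class(db) <- "claims_db"
  db
}

patient_row <- function(id, gender = "M", birth_year = 1950L,
                        cmu_c = FALSE, enrollment_day = 0L,
                        observation_end = 1095L,
                        death_day = NA_integer_) {
  data.table(patient_id = as.integer(id), gender = gender,
             birth_year = as.integer(birth_year), cmu_c = cmu_c,
             enrollment_day = as.integer(enrollment_day),
             observation_end = as.integer(observation_end),
             death_day = as.integer(death_day))
}

stay_row <- function(stay_id, id, admission, discharge,
                     primary = "I21.4", icu = FALSE,
                     category = "hospital") {
  data.table(stay_id = as.integer(stay_id), patient_id = as.integer(id),
             admission_day = as.integer(admission),
             discharge_day = as.integer(discharge),
             primary_code = primary, intensive_care = icu,
             hospital_category = category)
}

disp_row <- function(id, day, code = "B01AC24", packs = 1L,
                     units = 30L, ddd = 1) {
  data.table(patient_id = as.integer(id), day = as.integer(day),
             code = code, packs = as.integer(packs),
             units_per_pack = as.integer(units), ddd_per_unit = ddd)
}

## ---- independent oracles -----------------------------------------------

## day-by-day stock walk for exposure episodes, independent of the
## interval arithmetic used by track_episode()
oracle_episode <- function(own_days, own_supplies, other_days = integer(),
                           index_date = 0L, grace = 30L, horizon = 365L,
                           death_day = NA_integer_) {
  fu_end <- index_date + horizon
  if (!is.na(death_day)) fu_end <- min(fu_end, death_day)
  first <- min(own_days)
  keep <- own_days <= fu_end
  own_days <- own_days[keep]; own_supplies <- own_supplies[keep]
  other_days <- other_days[other_days > first & other_days <= fu_end]
  switch_day <- if (length(other_days)) min(other_days) else NA_integer_

  stock <- 0; cover_end <- NA_integer_; disc <- NA_integer_
  stopped_by_switch <- FALSE
  for (d in first:fu_end) {
    if (!is.na(cover_end) && d > cover_end + grace) {
      disc <- cover_end
      break
    }
    if (!is.na(switch_day) && d == switch_day) {
      stopped_by_switch <- TRUE
      break
    }
    if (d %in% own_days) {
      stock <- stock + sum(own_supplies[own_days == d])
      cover_end <- d + stock
    }
    if (stock > 0) stock <- stock - 1
  }
  if (is.na(disc) && !stopped_by_switch && !is.na(cover_end) &&
      cover_end + grace < fu_end) {
    disc <- cover_end
  }
  retention <- suppressWarnings(min(disc, switch_day, na.rm = TRUE))
  if (!is.finite(retention)) retention <- NA_integer_
  list(discontinuation_day = disc, switch_day = switch_day,
       retention_day = retention,
       exposure_end_day = if (is.na(retention)) fu_end else
         min(retention, fu_end))
}

## Bross bias multiplier recomputed from raw labels through explicit
## 2x2 tables
oracle_bross <- function(C, treated, outcome) {
  p1 <- mean(C[treated]); p0 <- mean(C[!treated])
  a <- sum(C == 1 & outcome); cc <- sum(C == 1 & !outcome)
  b <- sum(C == 0 & outcome); d <- sum(C == 0 & !outcome)
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.1; b <- b + 0.1; cc <- cc + 0.1; d <- d + 0.1
  }
  rr <- (a / (a + cc)) / (b / (b + d))
  if (rr < 1) rr <- 1 / rr
  abs(log((p1 * (rr - 1) + 1) / (p0 * (rr - 1) + 1)))
}

## exhaustive minimum-cost assignment for tiny instances
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

oracle_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= 6, m <= 6, n <= m)
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in all_perms(cols)) {
      v <- sum(cost[cbind(seq_len(n), p)])
      if (v < best) best <- v
    }
  }
  best
}

## ---- cached full-scale study run (shared across acceptance checks) -----

.study_cache <- new.env(parent = emptyenv())

full_scale_run <- function() {
  if (is.null(.study_cache$run)) {
    .study_cache$run <- suppressWarnings(
      run_study(study_config(n_patients = 20000, seed = 1)))
  }
  .study_cache$run
}
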