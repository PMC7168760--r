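## Synthetic claims-database generator.
##
## The generator emulates the relational structure of a national claims /
## hospital-discharge database: one row per dispensing, hospital stay,
## stay diagnosis, stay procedure, long-term-disease (LTD) registration,
## medical visit and lab claim, all dated as integer day offsets from the
## start of the extraction window (day 0; the inclusion year is days
## 365..729). Two latent patient states — a cardiometabolic burden and a
## frailty / bleeding-risk state — drive (i) treatment channeling among the
## three study antiplatelet agents, (ii) event hazards, and (iii) blocks of
## high-fidelity proxy codes in every claims dimension, which is the signal
## the high-dimensional propensity score is designed to exploit.

#' Simulation configuration for the synthetic claims database
#'
#' @param n_patients number of patients in the extracted database (>= 2)
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output
#' @param history_window_days length of the pre-index history window (days)
#' @param followup_days length of post-index follow-up (days)
#' @param latent_prevalence named prevalences of the two latent states
#' @param channeling_coefficients list with elements `ticagrelor` and
#'   `prasugrel`, each a named vector of log-odds contributions (relative to
#'   clopidogrel) for intercept, cardiometabolic, frailty, age (per year,
#'   centered at 66), female, stemi, nstemi
#' @param true_log_hazard_ratios list per drug of named log hazard ratios for
#'   the event components acs, stroke, death, bleeding (clopidogrel is the
#'   reference with all zeros)
#' @param baseline_hazards named events-per-person-year rates for acs,
#'   stroke, death, bleeding (all > 0)
#' @param hazard_coefficients list per component of named log-hazard
#'   contributions for cardiometabolic, frailty and age (per year)
#' @param code_vocab_sizes named background vocabulary sizes per dimension
#'   (diagnosis, drug, lab, procedure, visit, ltd), all >= 1
#' @param proxy_codes_per_latent named number of proxy codes per latent state
#'   per dimension
#' @param proxy_fidelity named vector lo/hi/bg_lo/bg_hi giving the range of
#'   per-code emission probabilities with and without the latent state
#' @param index_stay_fraction fraction of patients with an ACS index stay in
#'   the inclusion year
#' @param p_no_apa probability that an eligible patient receives no study
#'   antiplatelet after discharge
#' @param exclusion_rates named rates of the built-in selection-criterion
#'   exercisers (zero_duration, death_in_stay, prior_acs_30d, rehab,
#'   bad_category, short_history, emigration, minor)
#' @return object of class `sim_config`
#' @export
#' @examples
#' cfg <- simulation_config(n_patients = 500, seed = 7)
simulation_config <- function(
    n_patients = 20000L,
    seed = 1L,
    history_window_days = 365L,
    followup_days = 365L,
    latent_prevalence = c(cardiometabolic = 0.32, frailty = 0.32),
    channeling_coefficients = list(
      ticagrelor = c(intercept = 1.15, cardiometabolic = -1.6,
                     frailty = -0.8, age = -0.025, female = -0.15,
                     stemi = 0.3, nstemi = 0.1),
      prasugrel = c(intercept = -1.4, cardiometabolic = -0.5,
                    frailty = -0.6, age = -0.06, female = -0.3,
                    stemi = 0.5, nstemi = 0.2)),
    true_log_hazard_ratios = list(
      clopidogrel = c(acs = 0, stroke = 0, death = 0, bleeding = 0),
      ticagrelor = c(acs = log(0.8), stroke = log(0.8), death = log(0.8),
                     bleeding = log(1.25)),
      prasugrel = c(acs = log(0.9), stroke = log(0.9), death = log(0.9),
                    bleeding = log(1.4))),
    baseline_hazards = c(acs = 0.07, stroke = 0.015, death = 0.04,
                         bleeding = 0.03),
    hazard_coefficients = list(
      acs = c(cardiometabolic = 0.6, frailty = 0.2, age = 0.01),
      stroke = c(cardiometabolic = 0.3, frailty = 0.7, age = 0.02),
      death = c(cardiometabolic = 0.4, frailty = 0.7, age = 0.04),
      bleeding = c(cardiometabolic = 0.2, frailty = 1.0, age = 0.02)),
    code_vocab_sizes = c(diagnosis = 150L, drug = 150L, lab = 90L,
                         procedure = 60L, visit = 15L, ltd = 12L),
    proxy_codes_per_latent = c(diagnosis = 90L, drug = 90L, lab = 55L,
                               procedure = 20L, visit = 6L, ltd = 4L),
    proxy_fidelity = c(lo = 0.95, hi = 0.99, bg_lo = 0.001, bg_hi = 0.006),
    index_stay_fraction = 0.97,
    p_no_apa = 0.04,
    exclusion_rates = c(zero_duration = 0.008, death_in_stay = 0.012,
                        prior_acs_30d = 0.008, rehab = 0.010,
                        bad_category = 0.008, short_history = 0.007,
                        emigration = 0.005, minor = 0.004)) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 2)
    stop_config("n_patients must be a single integer >= 2")
  if (any(baseline_hazards <= 0))
    stop_config("baseline hazards must all be > 0")
  if (any(code_vocab_sizes < 1))
    stop_config("code vocabulary sizes must all be >= 1")
  if (history_window_days <= 0 || followup_days <= 0)
    stop_config("history and follow-up windows must be positive")
  stopifnot(all(c("acs", "stroke", "death", "bleeding") %in%
                  names(baseline_hazards)))
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    history_window_days = as.integer(history_window_days),
    followup_days = as.integer(followup_days),
    latent_prevalence = latent_prevalence,
    channeling_coefficients = channeling_coefficients,
    true_log_hazard_ratios = true_log_hazard_ratios,
    baseline_hazards = baseline_hazards,
    hazard_coefficients = hazard_coefficients,
    code_vocab_sizes = code_vocab_sizes,
    proxy_codes_per_latent = proxy_codes_per_latent,
    proxy_fidelity = proxy_fidelity,
    index_stay_fraction = index_stay_fraction,
    p_no_apa = p_no_apa,
    exclusion_rates = exclusion_rates)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients, "patients, seed", x$seed, "\n")
  invisible(x)
}

## channeling linear predictor for one comparator drug
channeling_logit <- function(co, latent_d, latent_f, age, female, stratum) {
  co[["intercept"]] +
    co[["cardiometabolic"]] * latent_d + co[["frailty"]] * latent_f +
    co[["age"]] * (age - 66) + co[["female"]] * female +
    co[["stemi"]] * (stratum == "STEMI") +
    co[["nstemi"]] * (stratum == "NSTEMI")
}

#' Simulate a synthetic claims database
#'
#' Generates the extracted population of an ACS (acute coronary syndrome)
#' claims study: nearly all patients carry an ACS-coded index hospitalization
#' in the inclusion year, preceded by at least one year of claims history,
#' with treatment choice after discharge drawn from a multinomial whose
#' log-odds are linear in the latent patient states (channeling) and
#' post-index event times exponential with hazard
#' baseline x exp(covariate effects + treatment log-HR). A small
#' configurable share of patients violates each selection criterion so that
#' cohort extraction is exercised end to end.
#'
#' @param config a [simulation_config()] object
#' @return object of class `claims_db`: a list of data.tables `patients`,
#'   `dispensings`, `hospital_stays`, `stay_diagnoses`, `stay_procedures`,
#'   `ltd_registrations`, `visits`, `lab_claims`, plus `meta` holding the
#'   config, the per-patient generative truth, and the code universe
#' @export
#' @examples
#' db <- simulate_claims(simulation_config(n_patients = 200, seed = 1))
#' nrow(db$patients)
simulate_claims <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_config("config must be created by simulation_config()")
  with_seed(config$seed, simulate_claims_impl(config))
}

simulate_claims_impl <- function(cfg) {
  n <- cfg$n_patients
  cs <- study_code_sets()
  universe <- build_code_universe(cfg$code_vocab_sizes,
                                 cfg$proxy_codes_per_latent,
                                 names(cfg$latent_prevalence),
                                 cfg$proxy_fidelity)

  ## ---- patient core ----------------------------------------------------
  id <- seq_len(n)
  female <- runif(n) < 0.32
  age <- pmin(pmax(as_day(rnorm(n, 66, 9)), 40L), 95L)
  latent_d <- runif(n) < cfg$latent_prevalence[["cardiometabolic"]]
  latent_f <- runif(n) < cfg$latent_prevalence[["frailty"]]
  stratum <- sample(c("STEMI", "NSTEMI", "UA"), n, replace = TRUE,
                    prob = c(0.38, 0.34, 0.28))
  has_index <- runif(n) < cfg$index_stay_fraction

  fates <- c("none", names(cfg$exclusion_rates))
  fate <- sample(fates, n, replace = TRUE,
                 prob = c(1 - sum(cfg$exclusion_rates), cfg$exclusion_rates))
  fate[!has_index] <- "no_index"
  age[fate == "minor"] <- sample(16:17, sum(fate == "minor"), replace = TRUE)

  ## ---- index stay ------------------------------------------------------
  admission <- 365L + sample.int(365L, n, replace = TRUE) - 1L
  admission[fate == "prior_acs_30d"] <-
    370L + sample.int(25L, sum(fate == "prior_acs_30d"), replace = TRUE) - 1L
  duration <- 2L + 4L * (stratum == "STEMI") + 3L * latent_d + rpois(n, 0.25)
  duration[fate == "zero_duration"] <- 0L
  discharge <- admission + duration

  icu <- runif(n) < ifelse(stratum == "STEMI", 0.965, 0.03)
  category <- ifelse(stratum == "STEMI", "teaching",
                     ifelse(latent_d, "hospital", "private"))
  flip <- runif(n) < 0.03
  category[flip] <- sample(c("teaching", "hospital", "private"), sum(flip),
                           replace = TRUE)
  category[fate == "bad_category"] <- "other"
  pci <- runif(n) < ifelse(stratum != "UA", 0.96, 0.03)
  cabg <- runif(n) < ifelse(stratum == "NSTEMI" & latent_d, 0.90, 0.004)

  index_primary <- character(n)
  index_primary[stratum == "UA"] <- cs$ua
  index_primary[stratum == "NSTEMI"] <- cs$nstemi
  n_st <- sum(stratum == "STEMI")
  index_primary[stratum == "STEMI"] <- sample(cs$stemi, n_st, replace = TRUE)

  enrollment <- integer(n)
  enrollment[fate == "short_history"] <-
    admission[fate == "short_history"] - 100L
  observation_end <- rep(1095L, n)
  observation_end[fate == "emigration"] <-
    discharge[fate == "emigration"] + 150L

  death_day <- rep(NA_integer_, n)
  dis <- fate == "death_in_stay"
  death_day[dis] <- admission[dis] + 1L

  anchor <- admission
  anchor[!has_index] <- 600L + sample.int(60L, sum(!has_index),
                                          replace = TRUE)

  stays <- list()
  diags <- list()
  procs <- list()
  disp <- list()
  ltds <- list()
  visits <- list()
  labs <- list()

  stays$index <- data.table::data.table(
    uid = paste0("IDX", id), patient_id = id, admission_day = admission,
    discharge_day = discharge, primary_code = index_primary,
    intensive_care = icu, hospital_category = category)[has_index]

  w <- which(fate == "prior_acs_30d")
  if (length(w)) {
    padm <- pmin(admission[w] - sample(6:29, length(w), replace = TRUE), 364L)
    stays$prior_acs <- data.table::data.table(
      uid = paste0("PRI", id[w]), patient_id = id[w], admission_day = padm,
      discharge_day = padm + 2L,
      primary_code = sample(cs$acs, length(w), replace = TRUE),
      intensive_care = FALSE, hospital_category = "hospital")
  }
  w <- which(fate == "rehab")
  if (length(w)) {
    radm <- discharge[w] + sample(3:25, length(w), replace = TRUE)
    stays$rehab <- data.table::data.table(
      uid = paste0("REH", id[w]), patient_id = id[w], admission_day = radm,
      discharge_day = radm + 20L, primary_code = "Z50.1",
      intensive_care = FALSE, hospital_category = "rehab")
  }

  if (any(pci & has_index)) {
    wpi <- which(pci & has_index)
    procs$pci <- data.table::data.table(
      uid = paste0("IDX", id[wpi]), patient_id = id[wpi],
      code = sample(cs$pci_procedures, length(wpi), replace = TRUE))
  }
  if (any(cabg & has_index)) {
    wc <- which(cabg & has_index)
    procs$cabg <- data.table::data.table(
      uid = paste0("IDX", id[wc]), patient_id = id[wc],
      code = sample(cs$cabg_procedures, length(wc), replace = TRUE))
  }

  ## ---- condition history (comorbidity algorithms + forced covariates) --
  hw <- cfg$history_window_days
  hist_day <- function(w) anchor[w] - sample.int(hw - 5L, length(w),
                                                 replace = TRUE) - 4L
  cmaps <- condition_code_maps()

  cond_draw <- function(driver, p_on, p_off) {
    runif(n) < ifelse(driver, p_on, p_off)
  }
  ## conditions kept deliberately close to deterministic functions of the
  ## latent states so that the derived Charlson index and history flags are
  ## balanced once the states are balanced
  has_mi      <- cond_draw(latent_d, 0.95, 0.010)
  has_diab    <- cond_draw(latent_d, 0.96, 0.010)
  has_htn     <- cond_draw(latent_d, 0.95, 0.020)
  has_copd    <- cond_draw(latent_f, 0.96, 0.010)
  has_ulcer   <- cond_draw(latent_f, 0.95, 0.008)
  has_cva     <- cond_draw(latent_f, 0.95, 0.010)
  asa_hist    <- cond_draw(latent_d, 0.96, 0.030)
  prior_apa   <- cond_draw(latent_d, 0.95, 0.020)
  acs_ltd_hx  <- cond_draw(latent_d, 0.95, 0.010)
  cmu_flag    <- cond_draw(latent_f, 0.96, 0.020)
  ## rare conditions, background only: exercise the full Charlson weight map
  has_sevliv  <- runif(n) < 0.004
  has_cancer  <- runif(n) < 0.010
  has_meta    <- runif(n) < 0.003
  has_renal   <- runif(n) < 0.008
  has_hiv     <- runif(n) < 0.001
  has_demen   <- runif(n) < 0.005

  cond_key <- local({i <- 0L; function() {i <<- i + 1L; paste0("c", i)}})
  emit_condition <- function(who, map, p_ltd, p_dx, p_drug = 0,
                             drug_codes = character(), n_disp = 3L,
                             large_pack = FALSE) {
    w <- which(who)
    if (!length(w)) return(invisible(NULL))
    key <- cond_key()
    if (p_ltd > 0 && length(map$ltd)) {
      wl <- w[runif(length(w)) < p_ltd]
      if (length(wl))
        ltds[[paste0(key, "l")]] <<- data.table::data.table(
          patient_id = id[wl],
          code = sample(rep(map$ltd, 2L), length(wl), replace = TRUE),
          start_day = pmax(0L, anchor[wl] -
                             sample.int(2000L, length(wl), replace = TRUE)),
          end_day = NA_integer_)
    }
    if (p_dx > 0 && length(map$dx)) {
      wd <- w[runif(length(w)) < p_dx]
      if (length(wd))
        diags[[paste0(key, "d")]] <<- data.table::data.table(
          patient_id = id[wd],
          code = sample(rep(map$dx, 2L), length(wd), replace = TRUE),
          type = "associated")
    }
    if (p_drug > 0 && length(drug_codes)) {
      wr <- w[runif(length(w)) < p_drug]
      if (length(wr)) {
        upp <- if (large_pack) 90L else 30L
        reps <- rep(wr, each = n_disp)
        disp[[paste0(key, "r")]] <<- data.table::data.table(
          patient_id = id[reps], day = hist_day(reps),
          code = sample(rep(drug_codes, 2L), length(reps), replace = TRUE),
          packs = 1L, units_per_pack = upp, ddd_per_unit = 1)
      }
    }
    invisible(NULL)
  }

  emit_condition(has_mi, cmaps$mi, p_ltd = 0, p_dx = 0.97)
  emit_condition(has_diab, cmaps$diabetes, p_ltd = 0.60, p_dx = 0.35,
                 p_drug = 0.90, drug_codes = cs$antidiabetic_atc)
  ## a slice of diabetics is identified only through the two-dispensing
  ## large-packaging rule
  emit_condition(has_diab & runif(n) < 0.08, cmaps$diabetes, 0, 0,
                 p_drug = 1, drug_codes = cs$antidiabetic_atc,
                 n_disp = 2L, large_pack = TRUE)
  emit_condition(has_htn, cmaps$hypertension, p_ltd = 0.70, p_dx = 0.60)
  emit_condition(has_copd, cmaps$copd, p_ltd = 0.60, p_dx = 0.75)
  emit_condition(has_ulcer, cmaps$ulcer, p_ltd = 0, p_dx = 0.96)
  emit_condition(has_cva, cmaps$cerebrovascular, p_ltd = 0.55, p_dx = 0.70)
  emit_condition(has_sevliv, cmaps$liver_severe, 0, 0.95)
  emit_condition(has_cancer, cmaps$cancer, 0.5, 0.6)
  emit_condition(has_meta, cmaps$metastatic, 0, 0.95)
  emit_condition(has_renal, cmaps$renal, 0.5, 0.6)
  emit_condition(has_hiv, cmaps$hiv, 0.9, 0.3)
  emit_condition(has_demen, cmaps$dementia, 0.5, 0.6)
  emit_condition(acs_ltd_hx, list(ltd = cs$acs_ltd), p_ltd = 1, p_dx = 0)

  w <- which(asa_hist)
  if (length(w)) {
    reps <- rep(w, each = 2L)
    disp$asa_hist <- data.table::data.table(
      patient_id = id[reps], day = hist_day(reps),
      code = cs$apa_atc[["ASA"]], packs = 1L, units_per_pack = 30L,
      ddd_per_unit = 1)
  }
  w <- which(prior_apa)
  if (length(w)) {
    reps <- rep(w, each = 2L)
    disp$prior_apa <- data.table::data.table(
      patient_id = id[reps], day = hist_day(reps),
      code = cs$apa_atc[["clopidogrel"]], packs = 1L, units_per_pack = 30L,
      ddd_per_unit = 1)
  }

  ## ---- proxy and background code emission ------------------------------
  latmat <- cbind(cardiometabolic = latent_d, frailty = latent_f)
  emit_universe <- function(dim_name) {
    u <- universe[dimension == dim_name]
    out <- vector("list", nrow(u))
    for (i in seq_len(nrow(u))) {
      p <- if (u$role[i] == "proxy") {
        ifelse(latmat[, u$latent[i]], u$p_on[i], u$p_off[i])
      } else rep(u$p_on[i], n)
      w <- which(runif(n) < p)
      if (!length(w)) next
      cnt <- 1L + rpois(length(w), 0.08)
      reps <- rep(w, cnt)
      out[[i]] <- list(patient_id = id[reps], day = hist_day(reps),
                       code = rep(u$code[i], length(reps)))
    }
    empty <- data.table::data.table(patient_id = integer(),
                                    day = integer(), code = character())
    data.table::rbindlist(c(list(empty), out))
  }

  dx_hist <- emit_universe("diagnosis")
  drug_hist <- emit_universe("drug")
  lab_hist <- emit_universe("lab")
  proc_hist <- emit_universe("procedure")
  visit_hist <- emit_universe("visit")
  ltd_hist <- emit_universe("ltd")

  if (nrow(drug_hist)) {
    disp$proxy <- drug_hist[, .(patient_id, day, code, packs = 1L,
                                units_per_pack = 30L, ddd_per_unit = 1)]
  }
  if (nrow(lab_hist)) labs$hist <- lab_hist
  if (nrow(visit_hist)) {
    visits$hist <- visit_hist[, .(patient_id, day, specialty = code)]
  }
  ## routine general-practice visits for everyone
  nv <- 2L + rpois(n, 2)
  reps <- rep(id, nv)
  visits$gp <- data.table::data.table(patient_id = reps,
                                      day = hist_day(reps),
                                      specialty = "GP")
  if (nrow(ltd_hist)) {
    ltds$proxy <- unique(ltd_hist[, .(patient_id, code)])[
      , .(patient_id, code,
          start_day = pmax(0L, anchor[patient_id] -
                             sample.int(2000L, .N, replace = TRUE)),
          end_day = NA_integer_)]
  }

  ## one history hospital stay per patient with any history diagnosis; all
  ## emitted diagnosis codes ride on it as linked/associated diagnoses
  extra_dx <- data.table::rbindlist(diags, use.names = TRUE)
  all_dx <- data.table::rbindlist(list(
    dx_hist[, .(patient_id, code, type = ifelse(runif(.N) < 0.15,
                                                "linked", "associated"))],
    extra_dx), use.names = TRUE)
  diags <- list()
  if (nrow(all_dx)) {
    hpat <- sort(unique(all_dx$patient_id))
    hadm <- anchor[hpat] - sample(30:330, length(hpat), replace = TRUE)
    hstay <- data.table::data.table(
      uid = paste0("HIS", hpat), patient_id = hpat, admission_day = hadm,
      discharge_day = hadm + 1L + rpois(length(hpat), 1),
      primary_code = sample(universe[dimension == "diagnosis" &
                                       role == "background"]$code,
                            length(hpat), replace = TRUE),
      intensive_care = FALSE, hospital_category = "hospital")
    stays$history <- hstay
    all_dx[, uid := paste0("HIS", patient_id)]
    diags$hist <- all_dx
    if (nrow(proc_hist)) {
      ph <- proc_hist[patient_id %in% hpat]
      procs$hist <- ph[, .(uid = paste0("HIS", patient_id), patient_id, code)]
    }
  }

  ## ---- treatment assignment and post-index dispensings -----------------
  lt <- channeling_logit(cfg$channeling_coefficients$ticagrelor,
                         latent_d, latent_f, age, female, stratum)
  lp <- channeling_logit(cfg$channeling_coefficients$prasugrel,
                         latent_d, latent_f, age, female, stratum)
  denom <- 1 + exp(lt) + exp(lp)
  p_clop <- 1 / denom
  p_tica <- exp(lt) / denom
  p_pras <- exp(lp) / denom
  u <- runif(n)
  drug <- ifelse(u < p_clop, "clopidogrel",
                 ifelse(u < p_clop + p_tica, "ticagrelor", "prasugrel"))
  drug[runif(n) < cfg$p_no_apa] <- "none"
  drug[!has_index | fate == "death_in_stay"] <- "none"

  delay_probs <- exp(-0.1 * (0:45))
  delay <- sample(0:45, n, replace = TRUE, prob = delay_probs)
  first_day <- discharge + delay

  treated <- which(drug != "none")
  fu_end <- pmin(discharge + cfg$followup_days + 60L, observation_end)
  max_refills <- 16L
  stop_p <- 0.035 + 0.03 * latent_f
  n_refills <- pmin(rgeom(n, stop_p), max_refills)
  switch_flag <- runif(n) < 0.03
  switch_at <- 1L + as.integer(runif(n) * pmax(1L, n_refills))
  other_drug <- vapply(drug, function(d) {
    if (d == "none") return("none")
    sample(setdiff(c("clopidogrel", "ticagrelor", "prasugrel"), d), 1L)
  }, character(1), USE.NAMES = FALSE)
  apa_code_map <- cs$apa_atc

  asa_index <- cond_draw(!latent_f, 0.96, 0.04)
  basi_user <- runif(n) < 0.90

  apa_rows <- vector("list", length(treated))
  for (k in seq_along(treated)) {
    i <- treated[k]
    gaps <- sample(26:40, max_refills + 1L, replace = TRUE)
    days <- first_day[i] + c(0L, cumsum(gaps))
    keep <- seq_len(min(n_refills[i] + 1L, max_refills + 1L))
    days <- days[keep]
    fams <- rep(drug[i], length(days))
    if (switch_flag[i] && switch_at[i] < length(days)) {
      fams[(switch_at[i] + 1L):length(days)] <- other_drug[i]
    }
    lim <- min(fu_end[i], if (is.na(death_day[i])) Inf else death_day[i] - 1L)
    ok <- days <= lim
    if (!any(ok)) next
    apa_rows[[k]] <- list(patient_id = rep(i, sum(ok)), day = days[ok],
                          code = unname(apa_code_map[fams[ok]]))
  }
  apa_dt <- data.table::rbindlist(apa_rows)
  if (nrow(apa_dt)) {
    disp$apa <- apa_dt[, .(patient_id, day, code, packs = 1L,
                           units_per_pack = 30L, ddd_per_unit = 1)]
    wasa <- apa_dt[asa_index[patient_id] == TRUE]
    if (nrow(wasa)) {
      disp$asa_index <- wasa[, .(patient_id, day,
                                 code = cs$apa_atc[["ASA"]], packs = 1L,
                                 units_per_pack = 30L, ddd_per_unit = 1)]
    }
    wbasi <- apa_dt[basi_user[patient_id] == TRUE]
    if (nrow(wbasi)) {
      disp$basi <- wbasi[, .(patient_id, day,
                             code = sample(unname(cs$basi_atc), .N,
                                           replace = TRUE),
                             packs = 1L, units_per_pack = 30L,
                             ddd_per_unit = 1)]
    }
  }

  ## ---- outcome events --------------------------------------------------
  comps <- c("acs", "stroke", "death", "bleeding")
  lhr <- matrix(0, n, length(comps), dimnames = list(NULL, comps))
  for (d in names(cfg$true_log_hazard_ratios)) {
    wd <- which(drug == d)
    if (length(wd))
      lhr[wd, ] <- matrix(cfg$true_log_hazard_ratios[[d]][comps],
                          length(wd), length(comps), byrow = TRUE)
  }
  event_day <- matrix(NA_integer_, n, length(comps),
                      dimnames = list(NULL, comps))
  atrisk <- has_index & fate != "death_in_stay"
  for (j in seq_along(comps)) {
    co <- cfg$hazard_coefficients[[comps[j]]]
    lambda <- cfg$baseline_hazards[[comps[j]]] *
      exp(co[["cardiometabolic"]] * latent_d + co[["frailty"]] * latent_f +
            co[["age"]] * (age - 66) + lhr[, j])
    t_days <- rexp(n, lambda / 365)
    ed <- discharge + pmax(1L, as_day(t_days))
    ed[!atrisk | ed > fu_end] <- NA_integer_
    event_day[, j] <- ed
  }
  ## death truncates everything after it
  dd <- event_day[, "death"]
  death_day[atrisk & !is.na(dd)] <- dd[atrisk & !is.na(dd)]
  for (j in which(comps != "death")) {
    lose <- !is.na(event_day[, j]) & !is.na(death_day) &
      event_day[, j] > death_day
    event_day[lose, j] <- NA_integer_
  }

  ev_stay <- function(comp, codes, icu_p) {
    w <- which(!is.na(event_day[, comp]))
    if (!length(w)) return(NULL)
    adm <- event_day[w, comp]
    data.table::data.table(
      uid = paste0(toupper(comp), id[w]), patient_id = id[w],
      admission_day = adm, discharge_day = adm + 2L + rpois(length(w), 1),
      primary_code = sample(rep(codes, 2L), length(w), replace = TRUE),
      intensive_care = runif(length(w)) < icu_p,
      hospital_category = sample(c("teaching", "hospital", "private"),
                                 length(w), replace = TRUE))
  }
  stays$ev_acs <- ev_stay("acs", cs$acs, 0.5)
  stays$ev_stroke <- ev_stay("stroke", cs$stroke, 0.4)
  stays$ev_bleed <- ev_stay("bleeding", cs$bleeding, 0.2)

  ## dispensings/visits/labs cannot postdate death or disenrollment
  empty_disp <- data.table::data.table(
    patient_id = integer(), day = integer(), code = character(),
    packs = integer(), units_per_pack = integer(), ddd_per_unit = numeric())
  all_disp <- data.table::rbindlist(c(list(empty_disp), disp),
                                    use.names = TRUE)
  lim_day <- ifelse(is.na(death_day), observation_end,
                    pmin(death_day, observation_end))
  all_disp <- all_disp[day <= lim_day[patient_id] & day >= 0L]
  all_visits <- data.table::rbindlist(visits, use.names = TRUE)
  all_visits <- all_visits[day <= lim_day[patient_id] & day >= 0L]
  empty_lab <- data.table::data.table(patient_id = integer(),
                                      day = integer(), code = character())
  all_labs <- data.table::rbindlist(c(list(empty_lab), labs),
                                    use.names = TRUE)
  if (nrow(all_labs))
    all_labs <- all_labs[day <= lim_day[patient_id] & day >= 0L]

  stay_dt <- data.table::rbindlist(stays[!vapply(stays, is.null,
                                                 logical(1))],
                                   use.names = TRUE)
  stay_dt <- stay_dt[admission_day <= lim_day[patient_id] &
                       admission_day >= 0L]
  data.table::setorder(stay_dt, patient_id, admission_day, discharge_day,
                       uid)
  stay_dt[, stay_id := .I]
  uid_map <- stay_dt[, .(uid, stay_id)]

  diag_dt <- data.table::rbindlist(diags, use.names = TRUE, fill = TRUE)
  if (nrow(diag_dt)) {
    diag_dt <- uid_map[diag_dt, on = "uid", nomatch = NULL]
    diag_dt <- diag_dt[, .(stay_id, patient_id, code, type)]
  } else {
    diag_dt <- data.table::data.table(stay_id = integer(),
                                      patient_id = integer(),
                                      code = character(),
                                      type = character())
  }
  proc_dt <- data.table::rbindlist(procs, use.names = TRUE)
  if (nrow(proc_dt)) {
    proc_dt <- uid_map[proc_dt, on = "uid", nomatch = NULL]
    proc_dt <- proc_dt[, .(stay_id, patient_id, code)]
  } else {
    proc_dt <- data.table::data.table(stay_id = integer(),
                                      patient_id = integer(),
                                      code = character())
  }
  stay_dt[, uid := NULL]
  data.table::setcolorder(stay_dt, c("stay_id", "patient_id",
                                     "admission_day", "discharge_day",
                                     "primary_code", "intensive_care",
                                     "hospital_category"))

  ltd_dt <- data.table::rbindlist(ltds, use.names = TRUE)
  if (!nrow(ltd_dt))
    ltd_dt <- data.table::data.table(patient_id = integer(),
                                     code = character(),
                                     start_day = integer(),
                                     end_day = integer())

  patients <- data.table::data.table(
    patient_id = id, gender = ifelse(female, "F", "M"),
    birth_year = 2013L - age, cmu_c = cmu_flag,
    enrollment_day = enrollment, observation_end = observation_end,
    death_day = death_day)

  truth <- data.table::data.table(
    patient_id = id, latent_cardiometabolic = latent_d,
    latent_frailty = latent_f, stratum = stratum, has_index = has_index,
    fate = fate, treatment = drug, p_clopidogrel = p_clop,
    p_ticagrelor = p_tica, p_prasugrel = p_pras,
    apa_delay = delay, index_admission_day = admission,
    index_discharge_day = discharge,
    event_acs = event_day[, "acs"], event_stroke = event_day[, "stroke"],
    event_death = event_day[, "death"],
    event_bleeding = event_day[, "bleeding"])

  data.table::setorder(all_disp, patient_id, day, code)
  data.table::setorder(all_visits, patient_id, day, specialty)
  if (nrow(all_labs)) data.table::setorder(all_labs, patient_id, day, code)
  data.table::setorder(ltd_dt, patient_id, code, start_day)

  db <- list(patients = patients, dispensings = all_disp,
             hospital_stays = stay_dt, stay_diagnoses = diag_dt,
             stay_procedures = proc_dt, ltd_registrations = ltd_dt,
             visits = all_visits, lab_claims = all_labs,
             meta = list(config = cfg, truth = truth,
                         code_universe = universe))
  class(db) <- "claims_db"
  validate_claims_db(db)
  db
}

#' @export
print.claims_db <- function(x, ...) {
  cat("<claims_db>", nrow(x$patients), "patients |",
      nrow(x$dispensings), "dispensings |", nrow(x$hospital_stays),
      "hospital stays |", nrow(x$visits), "visits\n")
  invisible(x)
}

#' Validate a claims database bundle
#'
#' Checks the schema invariants: discharge on or after admission, every
#' patient id referenced in an event table present in `patients`, and no
#' event starting after the patient's death day.
#'
#' @param db a `claims_db`
#' @return `db`, invisibly; errors on violation
#' @export
validate_claims_db <- function(db) {
  stopifnot(inherits(db, "claims_db"))
  tabs <- c("dispensings", "hospital_stays", "ltd_registrations", "visits",
            "lab_claims", "stay_diagnoses", "stay_procedures")
  ids <- db$patients$patient_id
  for (tb in tabs) {
    t <- db[[tb]]
    if (!nrow(t)) next
    if (!all(t$patient_id %in% ids))
      stop_config("table %s references unknown patient ids", tb)
  }
  hs <- db$hospital_stays
  if (nrow(hs) && any(hs$discharge_day < hs$admission_day))
    stop_config("hospital stay with discharge before admission")
  dd <- db$patients[!is.na(death_day)]
  if (nrow(dd)) {
    chk <- merge(db$dispensings, dd[, .(patient_id, death_day)],
                 by = "patient_id")
    if (nrow(chk) && any(chk$day > chk$death_day))
      stop_config("dispensing after death")
    chk <- merge(hs, dd[, .(patient_id, death_day)], by = "patient_id")
    if (nrow(chk) && any(chk$admission_day > chk$death_day))
      stop_config("hospital admission after death")
  }
  invisible(db)
}
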