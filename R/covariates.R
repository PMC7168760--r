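## Predefined (investigator-specified) confounders: demographics, index-stay
## features, treatment-history flags, comorbidity algorithms combining LTD
## registrations, hospital diagnoses and dispensing-count rules, and the
## age-weighted Charlson comorbidity index.

charlson_weights <- c(
  mi = 1, chf = 1, pvd = 1, cerebrovascular = 1, dementia = 1, copd = 1,
  connective = 1, ulcer = 1, liver_mild = 1, diabetes = 1,
  diabetes_organ = 2, renal = 2, hemiplegia = 2, cancer = 2,
  liver_severe = 3, metastatic = 6, hiv = 6)

#' Age-weighted Charlson comorbidity index
#'
#' Sums the standard condition weights (myocardial infarction, congestive
#' heart failure, peripheral vascular disease, cerebrovascular disease,
#' dementia, chronic pulmonary disease, connective tissue disease, ulcer,
#' mild liver disease and diabetes at weight 1; diabetes with end-organ
#' damage, renal disease, hemiplegia and any tumour at weight 2; moderate or
#' severe liver disease at weight 3; metastatic solid tumour and HIV/AIDS at
#' weight 6) plus one point per completed decade after age 50. Within each
#' severity pair (diabetes, liver, tumour) only the more severe condition
#' counts.
#'
#' @param flags named logical vector over (a subset of)
#'   `names(hdpscohort:::charlson_weights)`
#' @param age_years age at index (>= 0)
#' @return list with `score` (integer) and `category` (one of \[0-1\],
#'   \[2-3\], \[4-5\], \[6-7\], >7)
#' @export
#' @examples
#' charlson(c(mi = TRUE, diabetes_organ = TRUE), age_years = 72)
charlson <- function(flags, age_years) {
  if (age_years < 0) stop_config("negative age")
  f <- setNames(rep(FALSE, length(charlson_weights)),
                names(charlson_weights))
  if (length(flags) && any(!names(flags) %in% names(f)))
    stop_config("unknown Charlson condition(s): %s",
                paste(setdiff(names(flags), names(f)), collapse = ", "))
  f[names(flags)[as.logical(flags)]] <- TRUE
  ## severity hierarchies: the severe form supersedes the mild one
  if (f[["diabetes_organ"]]) f[["diabetes"]] <- FALSE
  if (f[["liver_severe"]]) f[["liver_mild"]] <- FALSE
  if (f[["metastatic"]]) f[["cancer"]] <- FALSE
  age_w <- if (age_years > 50) (age_years - 50) %/% 10 else 0L
  score <- as.integer(sum(charlson_weights[f]) + age_w)
  category <- cut(score, breaks = c(-0.5, 1.5, 3.5, 5.5, 7.5, Inf),
                  labels = c("[0-1]", "[2-3]", "[4-5]", "[6-7]", ">7"))
  list(score = score, category = as.character(category))
}

## conditions contributing to the Charlson score that the default synthetic
## condition maps can identify
charlson_conditions <- names(charlson_weights)

## comorbidity flags reported in the covariate record
comorbidity_conditions <- c("diabetes", "hypertension", "chf", "cad",
                            "pad", "stroke_hx", "bleeding_hx", "renal",
                            "liver_mild", "cancer", "copd")

#' Build the predefined covariate set for a cohort
#'
#' Every flag is computed strictly from events before the index admission:
#' hospital diagnoses, visits, lab claims and dispensings inside the
#' lookback window; LTD registrations with a start date before admission.
#' Diabetes additionally uses the dispensing-count rule (at least three
#' anti-diabetic dispensings, or at least two with one large package of 80+
#' units, inside the lookback window).
#'
#' @param db a `claims_db`
#' @param cohort cohort table from [select_cohort()]
#' @param lookback_days history window before admission (default 365)
#' @param maps condition code maps ([condition_code_maps()])
#' @return data.table, one row per cohort member: demographics, index-stay
#'   features, history flags, ATC level-3 history flags (`atc3_*`),
#'   comorbidity flags (`cm_*`), `charlson_score`, `charlson_category`
#' @export
build_covariates <- function(db, cohort, lookback_days = 365L,
                             maps = condition_code_maps()) {
  if (!all(cohort$patient_id %in% db$patients$patient_id))
    stop_config("cohort contains patients absent from the database")
  cs <- study_code_sets()
  out <- cohort[, .(patient_id, gender, age_years, stratum,
                    hospital_category, intensive_care, index_pci,
                    index_cabg, index_stay_duration, index_admission_day)]
  out <- merge(out, db$patients[, .(patient_id, cmu_c)], by = "patient_id")

  adm <- out[, .(patient_id, adm = index_admission_day)]
  win <- function(t, daycol = "day") {
    x <- merge(t, adm, by = "patient_id")
    x[x[[daycol]] >= adm - lookback_days & x[[daycol]] < adm]
  }

  disp_lb <- win(db$dispensings)
  stays_lb <- win(db$hospital_stays, "admission_day")
  dx_lb <- merge(db$stay_diagnoses,
                 stays_lb[, .(stay_id, patient_id)],
                 by = c("stay_id", "patient_id"))
  dx_all <- rbind(dx_lb[, .(patient_id, code)],
                  stays_lb[, .(patient_id, code = primary_code)])
  ltd_pre <- merge(db$ltd_registrations, adm, by = "patient_id")[
    start_day < adm]

  flag <- function(pids) out$patient_id %in% unique(pids)

  ## treatment history
  fam <- drug_dictionary()$family[
    match(disp_lb$code, drug_dictionary()$code)]
  out[, asa_history := flag(disp_lb$patient_id[!is.na(fam) &
                                                 fam == "ASA"])]
  out[, prior_apa := flag(disp_lb$patient_id[!is.na(fam) &
                                               fam %in% study_families])]
  out[, naive_apa := !prior_apa]

  ## history of ACS hospitalization (within lookback) and incident ACS
  out[, prior_acs := flag(stays_lb[primary_code %in% cs$acs, patient_id])]
  acs_stay_any <- merge(db$hospital_stays[primary_code %in% cs$acs],
                        adm, by = "patient_id")[admission_day < adm]
  acs_ltd <- ltd_pre[code %in% cs$acs_ltd]
  out[, incident_acs := !flag(c(acs_stay_any$patient_id,
                                acs_ltd$patient_id))]
  out[, incident_or_naive := incident_acs | naive_apa]

  ## ATC level-3 history flags (first four characters of the drug code)
  atc3 <- unique(substr(disp_lb$code, 1L, 4L))
  for (a in sort(atc3)) {
    out[, (paste0("atc3_", a)) :=
          flag(disp_lb$patient_id[substr(disp_lb$code, 1L, 4L) == a])]
  }

  ## condition detection: LTD before admission, diagnosis in lookback,
  ## or the dispensing-count rule where configured
  detect <- function(map, drug_rule = FALSE) {
    hit <- c(ltd_pre[code %in% map$ltd, patient_id],
             dx_all[code %in% map$dx, patient_id])
    if (drug_rule && length(map$atc)) {
      dr <- disp_lb[code %in% map$atc,
                    .(n = .N, large = any(units_per_pack >= 80)),
                    by = patient_id]
      hit <- c(hit, dr[n >= 3L | (n >= 2L & large), patient_id])
    }
    flag(hit)
  }

  cond_flags <- list()
  for (cn in charlson_conditions) {
    cond_flags[[cn]] <- detect(maps[[cn]], drug_rule = cn == "diabetes")
  }
  for (cn in comorbidity_conditions) {
    out[, (paste0("cm_", cn)) :=
          if (cn %in% names(cond_flags)) cond_flags[[cn]] else
            detect(maps[[cn]], drug_rule = cn == "diabetes")]
  }

  cmat <- do.call(cbind, cond_flags)
  ch <- vapply(seq_len(nrow(out)), function(i) {
    r <- charlson(setNames(cmat[i, ], colnames(cmat)), out$age_years[i])
    c(r$score, match(r$category, c("[0-1]", "[2-3]", "[4-5]", "[6-7]",
                                   ">7")))
  }, numeric(2))
  out[, charlson_score := as.integer(ch[1, ])]
  out[, charlson_category := c("[0-1]", "[2-3]", "[4-5]", "[6-7]",
                               ">7")[ch[2, ]]]
  out[, index_admission_day := NULL]
  out[]
}

#' Forced covariate design matrix for the propensity model
#'
#' Encodes the predefined patient characteristics entering the propensity
#' model: gender, age, CMU-c coverage, index-diagnosis stratum, index PCI /
#' CABG, intensive care, hospital category, index stay duration, ASA
#' history, incident-or-naive status and the Charlson score.
#'
#' @param covariates output of [build_covariates()]
#' @return numeric matrix, one row per patient, with named columns
#' @export
forced_covariate_matrix <- function(covariates) {
  cv <- covariates
  m <- cbind(
    female = as.numeric(cv$gender == "F"),
    age_years = as.numeric(cv$age_years),
    cmu_c = as.numeric(cv$cmu_c),
    stratum_stemi = as.numeric(cv$stratum == "STEMI"),
    stratum_nstemi = as.numeric(cv$stratum == "NSTEMI"),
    index_pci = as.numeric(cv$index_pci),
    index_cabg = as.numeric(cv$index_cabg),
    intensive_care = as.numeric(cv$intensive_care),
    hosp_teaching = as.numeric(cv$hospital_category == "teaching"),
    hosp_hospital = as.numeric(cv$hospital_category == "hospital"),
    index_stay_duration = as.numeric(cv$index_stay_duration),
    prior_acs = as.numeric(cv$prior_acs),
    asa_history = as.numeric(cv$asa_history),
    naive_apa = as.numeric(cv$naive_apa),
    incident_or_naive = as.numeric(cv$incident_or_naive),
    charlson_score = as.numeric(cv$charlson_score))
  rownames(m) <- as.character(cv$patient_id)
  m
}
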