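## Cohort extraction: apply the study's selection criteria to the claims
## database, producing the analyzable cohort (one row per included patient,
## with index date and index-diagnosis stratum) and a flow chart counting
## the patients dropped at each criterion, in order. A patient is counted
## against the first criterion that fails.

#' Selection criteria for the ACS new-user cohort
#'
#' Defaults encode the study design: first ACS hospitalization in the
#' inclusion year (synthetic days 365-729), no ACS hospitalization in the
#' 30 days before admission, admission to an acute-care hospital, stay
#' duration above zero days, adults, one year of database history before
#' admission, alive at discharge, one year of database follow-up after
#' discharge (patients dying within the year are retained), and no stay in
#' a rehabilitation centre in the 30 days after discharge.
#'
#' @param inclusion_start,inclusion_end day bounds of the inclusion year
#' @param acs_primary_codes primary diagnosis codes defining ACS
#' @param stratum_map named vector mapping ACS primary codes to strata
#'   (UA / STEMI / NSTEMI)
#' @param min_age_years minimum age at index
#' @param history_days required pre-admission database history
#' @param followup_days required post-discharge follow-up in the database
#' @param washout_prior_acs_days ACS-free window before admission
#' @param rehab_exclusion_days window after discharge screened for
#'   rehabilitation stays
#' @param allowed_hospital_categories acceptable index hospital categories
#' @return object of class `selection_criteria`
#' @export
selection_criteria <- function(
    inclusion_start = 365L, inclusion_end = 729L,
    acs_primary_codes = study_code_sets()$acs,
    stratum_map = acs_stratum_map(),
    min_age_years = 18L,
    history_days = 365L,
    followup_days = 365L,
    washout_prior_acs_days = 30L,
    rehab_exclusion_days = 30L,
    allowed_hospital_categories = c("teaching", "hospital", "private")) {
  if (inclusion_end < inclusion_start)
    stop_config("inclusion window is empty")
  if (!length(acs_primary_codes)) stop_config("ACS code set is empty")
  if (history_days <= 0 || followup_days <= 0 ||
      washout_prior_acs_days <= 0 || rehab_exclusion_days <= 0)
    stop_config("all windows must be positive")
  structure(list(
    inclusion_start = as.integer(inclusion_start),
    inclusion_end = as.integer(inclusion_end),
    acs_primary_codes = acs_primary_codes,
    stratum_map = stratum_map,
    min_age_years = as.integer(min_age_years),
    history_days = as.integer(history_days),
    followup_days = as.integer(followup_days),
    washout_prior_acs_days = as.integer(washout_prior_acs_days),
    rehab_exclusion_days = as.integer(rehab_exclusion_days),
    allowed_hospital_categories = allowed_hospital_categories),
    class = "selection_criteria")
}

#' Select the study cohort and build the flow chart
#'
#' The candidate index stay per patient is the first ACS-coded
#' hospitalization whose admission falls in the inclusion window (ties on
#' admission day broken by earlier discharge, then lower stay id). The
#' listed criteria are then applied in the study's order; each excluded
#' patient is counted at the first criterion that fails. The index date is
#' the discharge day of the index stay, and the index-diagnosis stratum is
#' assigned from the primary code via the stratum map.
#'
#' @param db a `claims_db`
#' @param criteria a [selection_criteria()] object
#' @return list with `cohort` (data.table: patient_id,
#'   index_admission_day, index_date, stratum, hospital_category,
#'   intensive_care, index_pci, index_cabg, index_stay_duration, age_years,
#'   gender) and `flowchart` (data.table: criterion, n_remaining)
#' @export
select_cohort <- function(db, criteria = selection_criteria()) {
  stopifnot(inherits(db, "claims_db"), inherits(criteria,
                                                "selection_criteria"))
  cr <- criteria
  hs <- db$hospital_stays
  pat <- db$patients

  acs_stays <- hs[primary_code %in% cr$acs_primary_codes]
  cand <- acs_stays[admission_day >= cr$inclusion_start &
                      admission_day <= cr$inclusion_end]
  data.table::setorder(cand, patient_id, admission_day, discharge_day,
                       stay_id)
  idx <- cand[, .SD[1L], by = patient_id]

  steps <- character()
  counts <- integer()
  note <- function(label, n) {
    steps <<- c(steps, label)
    counts <<- c(counts, n)
  }
  note("ACS hospitalisation with admission in inclusion year", nrow(idx))

  idx <- merge(idx, pat, by = "patient_id")
  unknown <- setdiff(idx$primary_code, names(cr$stratum_map))
  if (length(unknown))
    stop_config("ACS primary code(s) without stratum mapping: %s",
                paste(unknown, collapse = ", "))

  apply_step <- function(label, keep) {
    idx <<- idx[keep]
    note(label, nrow(idx))
  }

  apply_step("index stay starts and ends within inclusion year",
             idx$discharge_day <= cr$inclusion_end)

  ## ACS-free 30-day window before admission
  prior <- merge(acs_stays, idx[, .(patient_id,
                                    index_adm = admission_day,
                                    index_sid = stay_id)],
                 by = "patient_id")
  bad <- prior[stay_id != index_sid &
                 admission_day < index_adm &
                 admission_day >= index_adm - cr$washout_prior_acs_days,
               unique(patient_id)]
  apply_step("no ACS hospitalisation in the 30 days before admission",
             !(idx$patient_id %in% bad))

  apply_step("index stay in an acute-care hospital",
             idx$hospital_category %in% cr$allowed_hospital_categories)

  apply_step("index hospitalisation duration more than zero days",
             idx$discharge_day > idx$admission_day)

  ## synthetic calendar: year of index = 2012 + floor(admission/365);
  ## age from year of birth only, as recorded in the claims
  age <- (2012L + (idx$admission_day %/% 365L)) - idx$birth_year
  apply_step("adult patients (18 years or more)", age >= cr$min_age_years)

  apply_step("one year of database history before admission",
             idx$enrollment_day <= idx$admission_day - cr$history_days)

  apply_step("alive at discharge of index hospitalisation",
             is.na(idx$death_day) | idx$death_day > idx$discharge_day)

  apply_step("one year of database follow-up after index (deaths retained)",
             (!is.na(idx$death_day)) |
               idx$observation_end >= idx$discharge_day + cr$followup_days)

  rehab <- hs[hospital_category == "rehab"]
  if (nrow(rehab)) {
    reh <- merge(rehab, idx[, .(patient_id, index_dis = discharge_day)],
                 by = "patient_id")
    badr <- reh[admission_day >= index_dis &
                  admission_day <= index_dis + cr$rehab_exclusion_days,
                unique(patient_id)]
  } else badr <- integer()
  apply_step("no rehabilitation-centre stay in the 30 days after discharge",
             !(idx$patient_id %in% badr))

  cohort <- idx[, .(
    patient_id,
    index_admission_day = admission_day,
    index_date = discharge_day,
    stratum = unname(cr$stratum_map[primary_code]),
    hospital_category, intensive_care,
    index_stay_duration = discharge_day - admission_day,
    gender,
    age_years = (2012L + (admission_day %/% 365L)) - birth_year,
    death_day, observation_end)]

  sp <- db$stay_procedures
  cs <- study_code_sets()
  idx_sid <- idx[, .(patient_id, stay_id)]
  pci_pat <- merge(sp[code %in% cs$pci_procedures], idx_sid,
                   by = c("patient_id", "stay_id"))$patient_id
  cabg_pat <- merge(sp[code %in% cs$cabg_procedures], idx_sid,
                    by = c("patient_id", "stay_id"))$patient_id
  cohort[, `:=`(index_pci = patient_id %in% pci_pat,
                index_cabg = patient_id %in% cabg_pat)]

  flowchart <- data.table::data.table(criterion = steps,
                                      n_remaining = counts)
  if (is.unsorted(rev(flowchart$n_remaining)))
    stop("internal error: flow chart counts increased")
  list(cohort = cohort[], flowchart = flowchart)
}
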