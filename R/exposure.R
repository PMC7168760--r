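## Exposure derivation from dispensing claims: treatment-group assignment
## (first study antiplatelet dispensed within 30 days of discharge),
## episode tracking with a running stock of drug supply in DDD-days
## (carryover of unconsumed supply from earlier dispensings, a 30-day grace
## period for detecting discontinuation), switch detection, retention, and
## the medication possession ratio (MPR).

study_families <- c("clopidogrel", "prasugrel", "ticagrelor")

#' MPR category partition
#'
#' Categorizes an MPR percentage into the seven study categories:
#' 0, ]0-20[, [20-40[, [40-60[, [60-80[, [80-100[, 100. The two endpoints
#' are singleton categories.
#'
#' @param mpr_percent numeric vector in \[0, 100\]
#' @return factor with the seven category levels
#' @export
#' @examples
#' mpr_category(c(0, 10, 100))
mpr_category <- function(mpr_percent) {
  if (any(mpr_percent < 0 | mpr_percent > 100, na.rm = TRUE))
    stop_config("mpr_percent must be within [0, 100]")
  lev <- c("0", "]0-20[", "[20-40[", "[40-60[", "[60-80[", "[80-100[",
           "100")
  out <- character(length(mpr_percent))
  out[mpr_percent == 0] <- "0"
  out[mpr_percent > 0 & mpr_percent < 20] <- "]0-20["
  out[mpr_percent >= 20 & mpr_percent < 40] <- "[20-40["
  out[mpr_percent >= 40 & mpr_percent < 60] <- "[40-60["
  out[mpr_percent >= 60 & mpr_percent < 80] <- "[60-80["
  out[mpr_percent >= 80 & mpr_percent < 100] <- "[80-100["
  out[mpr_percent == 100] <- "100"
  factor(out, levels = lev)
}

#' Assign the treatment group for one patient
#'
#' The first dispensing of a study antiplatelet (clopidogrel, prasugrel or
#' ticagrelor) within `window_days` of the index date (discharge) defines
#' the treatment group. Patients whose first study-drug dispensing falls
#' beyond the window are not included (returns `NULL`). An ASA dispensing
#' on the same day as the first study-drug dispensing sets `asa_at_index`.
#'
#' @param dispensings data.table of the patient's dispensings (day, code,
#'   packs, units_per_pack, ddd_per_unit), sorted by day
#' @param index_date index date (discharge day)
#' @param dict drug dictionary ([drug_dictionary()])
#' @param window_days assignment window after index (default 30)
#' @return list with initial_family, first_dispensing_day, asa_at_index, or
#'   `NULL` when no study drug is dispensed in the window
#' @export
assign_treatment_group <- function(dispensings, index_date,
                                   dict = drug_dictionary(),
                                   window_days = 30L) {
  if (!nrow(dispensings)) return(NULL)
  if (any(dispensings$day < 0)) stop_config("negative dispensing day")
  fam <- dict$family[match(dispensings$code, dict$code)]
  ## the first study-drug dispensing on or after the index date defines the
  ## group; dispensings before discharge are treatment history, not
  ## initiation
  is_study <- !is.na(fam) & fam %in% study_families &
    dispensings$day >= index_date
  if (!any(is_study)) return(NULL)
  first_idx <- which(is_study)[which.min(dispensings$day[is_study])]
  d0 <- dispensings$day[first_idx]
  if (d0 > index_date + window_days) return(NULL)
  asa <- any(!is.na(fam) & fam == "ASA" & dispensings$day == d0)
  list(initial_family = fam[first_idx], first_dispensing_day = d0,
       asa_at_index = asa)
}

#' Track one patient's exposure episode
#'
#' Walks the dispensings of the initial drug keeping a running stock of
#' supply in DDD-days, with full carryover of unconsumed supply.
#' Discontinuation is declared at the first gap exceeding the current
#' supply plus the grace period and dated at the exhaustion of supply
#' (last dispensing day plus remaining supply, without the grace period).
#' A dispensing of a different study antiplatelet sets the switch day.
#' Retention ends at the earlier of discontinuation and switch; exposure
#' runs from the index date to the retention day, or to the end of
#' follow-up (`index_date + horizon_days`, truncated at death) when neither
#' occurs. MPR is 100 x DDD of the initial drug dispensed during exposure
#' divided by exposure days, capped at 100.
#'
#' @param dispensings the patient's dispensings (all drugs), sorted by day
#' @param index_date index date
#' @param initial_family family of the initial study drug
#' @param first_dispensing_day day of the first study-drug dispensing
#' @param dict drug dictionary
#' @param grace_days grace period for discontinuation detection
#' @param horizon_days follow-up horizon after index
#' @param death_day death day or `NA`
#' @return list: initial_family, first_dispensing_day, discontinuation_day,
#'   switch_day, retention_day, exposure_end_day, exposure_days,
#'   mpr_percent, mpr_category
#' @export
track_episode <- function(dispensings, index_date, initial_family,
                          first_dispensing_day, dict = drug_dictionary(),
                          grace_days = 30L, horizon_days = 365L,
                          death_day = NA_integer_) {
  fam <- dict$family[match(dispensings$code, dict$code)]
  if (anyNA(fam)) {
    unknown <- unique(dispensings$code[is.na(fam)])
    stop_config("drug dictionary is missing dispensed code(s): %s",
                paste(unknown, collapse = ", "))
  }
  fu_end <- index_date + horizon_days
  if (!is.na(death_day)) fu_end <- min(fu_end, death_day)

  own <- which(fam == initial_family & dispensings$day >=
                 first_dispensing_day & dispensings$day <= fu_end)
  own <- own[order(dispensings$day[own])]
  other <- which(fam %in% setdiff(study_families, initial_family) &
                   dispensings$day > first_dispensing_day &
                   dispensings$day <= fu_end)
  switch_day <- if (length(other)) min(dispensings$day[other]) else
    NA_integer_

  ddd <- dict$ddd_per_unit[match(dispensings$code, dict$code)]
  upp <- ifelse(is.na(dispensings$units_per_pack),
                dict$units_per_pack[match(dispensings$code, dict$code)],
                dispensings$units_per_pack)
  supply <- dispensings$packs * upp * ddd

  discontinuation_day <- NA_integer_
  cover_end <- NA_real_
  for (i in own) {
    d <- dispensings$day[i]
    if (is.na(cover_end)) {
      cover_end <- d + supply[i]
    } else if (d <= cover_end + grace_days) {
      ## refill within supply + grace: carry over unconsumed stock
      cover_end <- max(cover_end, d) + supply[i]
    } else {
      discontinuation_day <- as.integer(cover_end)
      break
    }
  }
  if (is.na(discontinuation_day) && !is.na(cover_end) &&
      cover_end + grace_days < fu_end) {
    discontinuation_day <- as.integer(cover_end)
  }
  ## a switch occurring before the discontinuation could be detected
  ## (exhaustion + grace) pre-empts it: the patient moved to another study
  ## drug, they did not stop antiplatelet therapy
  if (!is.na(discontinuation_day) && !is.na(switch_day) &&
      switch_day <= discontinuation_day + grace_days) {
    discontinuation_day <- NA_integer_
  }

  retention_day <- suppressWarnings(
    min(discontinuation_day, switch_day, na.rm = TRUE))
  if (!is.finite(retention_day)) retention_day <- NA_integer_

  exposure_end <- if (is.na(retention_day)) fu_end else
    min(retention_day, fu_end)
  exposure_days <- max(0L, as.integer(exposure_end) - index_date)

  in_window <- own[dispensings$day[own] <= exposure_end]
  ddd_dispensed <- sum(supply[in_window])
  mpr <- if (exposure_days > 0) {
    min(100, 100 * ddd_dispensed / exposure_days)
  } else 0
  list(initial_family = initial_family,
       first_dispensing_day = as.integer(first_dispensing_day),
       discontinuation_day = discontinuation_day,
       switch_day = if (is.na(switch_day)) NA_integer_ else
         as.integer(switch_day),
       retention_day = if (is.na(retention_day)) NA_integer_ else
         as.integer(retention_day),
       exposure_end_day = as.integer(exposure_end),
       exposure_days = exposure_days,
       mpr_percent = mpr,
       mpr_category = as.character(mpr_category(mpr)))
}

#' Derive exposure episodes for an entire cohort
#'
#' Applies [assign_treatment_group()] and [track_episode()] to every cohort
#' member. Patients without a study-drug dispensing within the assignment
#' window are returned with treatment "none" and are excluded from treated
#' analyses downstream.
#'
#' @param db a `claims_db`
#' @param cohort cohort table from [select_cohort()]
#' @param dict drug dictionary; by default built from the dispensed codes
#' @param window_days assignment window (days after index)
#' @param grace_days discontinuation grace period
#' @param horizon_days follow-up horizon
#' @return data.table, one row per cohort member, with the episode fields
#'   (treatment = initial family or "none") and `asa_at_index`
#' @export
derive_exposure <- function(db, cohort, dict = NULL, window_days = 30L,
                            grace_days = 30L, horizon_days = 365L) {
  if (is.null(dict))
    dict <- drug_dictionary(extra_codes = unique(db$dispensings$code))
  disp <- db$dispensings[patient_id %in% cohort$patient_id]
  data.table::setorder(disp, patient_id, day)
  split_disp <- split(disp, by = "patient_id", keep.by = TRUE)

  rows <- vector("list", nrow(cohort))
  for (k in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[k]
    idx <- cohort$index_date[k]
    dd <- cohort$death_day[k]
    pd <- split_disp[[as.character(pid)]]
    if (is.null(pd)) pd <- disp[0L]
    grp <- assign_treatment_group(pd, idx, dict, window_days)
    if (is.null(grp)) {
      rows[[k]] <- list(patient_id = pid, treatment = "none",
                        first_dispensing_day = NA_integer_,
                        asa_at_index = NA,
                        discontinuation_day = NA_integer_,
                        switch_day = NA_integer_,
                        retention_day = NA_integer_,
                        exposure_end_day = NA_integer_,
                        exposure_days = NA_integer_,
                        mpr_percent = NA_real_,
                        mpr_category = NA_character_)
      next
    }
    ep <- track_episode(pd, idx, grp$initial_family,
                        grp$first_dispensing_day, dict, grace_days,
                        horizon_days, dd)
    rows[[k]] <- c(list(patient_id = pid,
                        treatment = grp$initial_family),
                   ep[c("first_dispensing_day", "discontinuation_day",
                        "switch_day", "retention_day", "exposure_end_day",
                        "exposure_days", "mpr_percent", "mpr_category")],
                   list(asa_at_index = grp$asa_at_index))
  }
  data.table::rbindlist(rows, use.names = TRUE)
}
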