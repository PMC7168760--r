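## Endpoint definition, event-time derivation during the initial exposure
## period, person-time incidence, Kaplan-Meier estimation, and between-arm
## comparison by Cox proportional hazards (more than 100 events) or
## (quasi-)Poisson regression with a person-time offset (100 events or
## fewer).

#' Endpoint definitions
#'
#' Each endpoint is a set of component event selectors; a composite takes
#' the first of its component events. Hospital components select stays by
#' primary diagnosis code (optionally requiring an intensive-care stay);
#' the revascularization component selects stays carrying a PCI/CABG
#' procedure code; `death` selects the death date.
#'
#' @return named list of endpoint definitions
#' @export
endpoint_definitions <- function() {
  cs <- study_code_sets()
  hosp <- function(codes, icu = FALSE) list(kind = "hospital",
                                            codes = codes, icu = icu)
  proc <- function(codes) list(kind = "procedure", codes = codes)
  death <- list(kind = "death")
  list(
    primary_effectiveness = list(acs = hosp(cs$acs),
                                 stroke = hosp(cs$stroke), death = death),
    secondary_effectiveness_revasc = list(
      acs = hosp(cs$acs), stroke = hosp(cs$stroke),
      revasc = proc(c(cs$pci_procedures, cs$cabg_procedures)),
      death = death),
    secondary_effectiveness_icu = list(
      acs_icu = hosp(cs$acs, icu = TRUE), stroke = hosp(cs$stroke),
      death = death),
    primary_safety = list(bleeding = hosp(cs$bleeding)),
    death = list(death = death),
    acs = list(acs = hosp(cs$acs)),
    stroke = list(stroke = hosp(cs$stroke)),
    revascularization = list(
      revasc = proc(c(cs$pci_procedures, cs$cabg_procedures))),
    acs_icu = list(acs_icu = hosp(cs$acs, icu = TRUE)))
}

#' Resolve a death date known only to the month
#'
#' Applies the day-15 convention: a death date with year and month but no
#' day is set to the 15th of the month; when a hospitalization of the same
#' patient ends in that month after the 15th, the hospitalization end date
#' is used instead.
#'
#' @param month_start_day epoch day of the first day of the death month
#' @param month_length days in the month (synthetic calendar: 30)
#' @param stay_end_days epoch days on which the patient's hospitalizations
#'   ended (may be empty)
#' @return resolved epoch day of death
#' @export
resolve_death_day <- function(month_start_day, month_length = 30L,
                              stay_end_days = integer()) {
  day15 <- month_start_day + 14L
  in_month <- stay_end_days[stay_end_days >= month_start_day &
                              stay_end_days < month_start_day +
                              month_length]
  late <- in_month[in_month > day15]
  if (length(late)) max(late) else day15
}

#' Derive per-patient event times for one endpoint
#'
#' Follow-up runs from the first dispensing day (so that the days between
#' discharge and treatment start contribute no person-time) to the
#' earliest of the endpoint event, the end of the initial exposure period
#' (retention, death or day 365 after index) and the end of observation.
#' The event indicator is 1 only when the event occurs during the exposure
#' period.
#'
#' @param db a `claims_db`
#' @param episodes exposure table from [derive_exposure()], restricted to
#'   treated patients
#' @param endpoint one element of [endpoint_definitions()]
#' @return data.table: patient_id, time (days, > 0), event (0/1),
#'   event_day
#' @export
derive_event_times <- function(db, episodes, endpoint) {
  ep <- episodes[treatment != "none"]
  if (!nrow(ep)) stop_config("no treated episodes supplied")
  hs <- db$hospital_stays
  cand <- list()
  for (comp in endpoint) {
    if (comp$kind == "hospital") {
      if (!length(comp$codes)) stop_config("endpoint has empty code set")
      sel <- hs[primary_code %in% comp$codes]
      if (isTRUE(comp$icu)) sel <- sel[intensive_care == TRUE]
      cand$h <- rbind(cand$h,
                      sel[, .(patient_id, event_day = admission_day)])
    } else if (comp$kind == "procedure") {
      sp <- db$stay_procedures[code %in% comp$codes]
      sel <- merge(hs, unique(sp[, .(stay_id, patient_id)]),
                   by = c("stay_id", "patient_id"))
      cand$p <- rbind(cand$p,
                      sel[, .(patient_id, event_day = admission_day)])
    } else if (comp$kind == "death") {
      dd <- db$patients[!is.na(death_day),
                        .(patient_id, event_day = death_day)]
      cand$d <- rbind(cand$d, dd)
    } else stop_config("unknown endpoint component kind '%s'", comp$kind)
  }
  ev <- data.table::rbindlist(cand)

  out <- ep[, .(patient_id, first_dispensing_day, exposure_end_day)]
  ev <- merge(ev, out, by = "patient_id")
  ev <- ev[event_day >= first_dispensing_day &
             event_day <= exposure_end_day]
  first_ev <- if (nrow(ev)) {
    ev[, .(event_day = min(event_day)), by = patient_id]
  } else {
    data.table::data.table(patient_id = integer(),
                           event_day = integer())
  }
  out <- merge(out, first_ev, by = "patient_id", all.x = TRUE)
  out[, event := as.integer(!is.na(event_day))]
  out[, end_day := ifelse(event == 1L, event_day, exposure_end_day)]
  ## same-day events get half a day of person-time
  out[, time := pmax(end_day - first_dispensing_day, 0.5)]
  out[, .(patient_id, time, event, event_day)]
}

#' Person-time incidence and Kaplan-Meier curve
#'
#' @param times follow-up times in days (> 0)
#' @param events 0/1 event indicators
#' @return list: events, person_years, rate_per_100py, km (data.table:
#'   time, n_risk, n_event, survival)
#' @export
estimate_incidence <- function(times, events) {
  if (any(times <= 0)) stop_config("all follow-up times must be > 0")
  py <- sum(times) / 365
  if (py == 0) stop_config("zero person-time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  km <- data.table::data.table(time = fit$time, n_risk = fit$n.risk,
                               n_event = fit$n.event,
                               survival = fit$surv)
  list(events = sum(events), person_years = py,
       rate_per_100py = 100 * sum(events) / py, km = km)
}

#' Compare incidence between two arms
#'
#' With more than 100 events overall, a Cox proportional-hazards model is
#' fitted (with a pair-clustered robust variance when matched pairs are
#' supplied) and the proportionality of each covariate is checked on
#' scaled Schoenfeld residuals (violations are recorded, not fatal). With
#' 100 events or fewer, a Poisson model with a log person-time offset is
#' used, upgraded to quasi-Poisson when the Pearson dispersion statistic
#' exceeds 1. The estimate is the hazard (or rate) ratio for
#' treated vs comparator.
#'
#' @param times follow-up times in days
#' @param events 0/1 indicators
#' @param treated logical vector, TRUE = treated arm
#' @param covariates optional numeric matrix / data.frame of adjustment
#'   covariates
#' @param pair_id optional pair identifiers for matched analyses (robust
#'   clustered variance)
#' @param stratified when TRUE (and `pair_id` is given), the Cox model is
#'   stratified by pair instead of using a marginal fit with clustered
#'   variance; the stratified fit targets the conditional (within-pair)
#'   hazard ratio, which is the generative parameter in simulations, while
#'   the marginal fit is attenuated towards 1 by hazard-ratio
#'   non-collapsibility under outcome heterogeneity
#' @return object of class `survival_result`
#' @export
compare_incidence <- function(times, events, treated, covariates = NULL,
                              pair_id = NULL, stratified = FALSE) {
  tr <- as.logical(treated)
  if (!any(tr) || all(tr)) stop_config("both arms must be present")
  if (sum(events[tr]) == 0 && sum(events[!tr]) == 0)
    stop_config("no events in either arm; comparison undefined")
  per_arm <- function(w) {
    list(events = sum(events[w]), person_years = sum(times[w]) / 365,
         rate_per_100py = 100 * sum(events[w]) / (sum(times[w]) / 365))
  }
  arms <- list(treated = per_arm(tr), comparator = per_arm(!tr))

  dat <- data.frame(time = times, event = events, arm = as.numeric(tr))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
  }
  adj <- if (!is.null(covariates)) colnames(covariates) else character()
  total_events <- sum(events)
  ph_diag <- NULL

  if (total_events > 100) {
    model_used <- "cox"
    rhs <- paste(c("arm", adj), collapse = " + ")
    if (!is.null(pair_id)) {
      dat$.pair <- pair_id
      rhs_full <- if (stratified) paste(rhs, "+ strata(.pair)") else
        paste(rhs, "+ cluster(.pair)")
      f <- as.formula(paste("survival::Surv(time, event) ~", rhs_full))
      if (stratified) model_used <- "cox_stratified"
    } else {
      f <- as.formula(paste("survival::Surv(time, event) ~", rhs))
    }
    fit <- survival::coxph(f, data = dat)
    sm <- summary(fit)
    est <- unname(coef(fit)["arm"])
    se <- if (!is.null(pair_id) && !stratified)
      sm$coefficients["arm", "robust se"] else
        sm$coefficients["arm", "se(coef)"]
    ph_diag <- tryCatch({
      zp <- survival::cox.zph(fit)
      data.table::data.table(covariate = rownames(zp$table),
                             p = zp$table[, "p"])
    }, error = function(e) NULL)
  } else {
    rhs <- paste(c("arm", adj), collapse = " + ")
    f <- as.formula(paste("event ~", rhs, "+ offset(log(time / 365))"))
    fit <- glm(f, family = poisson(), data = dat)
    disp <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
    if (is.finite(disp) && disp > 1) {
      model_used <- "quasi_poisson"
      fit <- glm(f, family = stats::quasipoisson(), data = dat)
    } else {
      model_used <- "poisson"
    }
    sm <- summary(fit)
    est <- unname(coef(fit)["arm"])
    se <- sm$coefficients["arm", "Std. Error"]
  }
  z <- est / se
  res <- list(
    arms = arms, model = model_used,
    estimate = exp(est), log_estimate = est, se = se,
    ci = exp(est + c(-1, 1) * qnorm(0.975) * se),
    wald_p = 2 * pnorm(-abs(z)),
    total_events = total_events,
    proportionality = ph_diag)
  class(res) <- "survival_result"
  res
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf(
    "<survival_result> %s: ratio %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$model, x$estimate, x$ci[1], x$ci[2], x$wald_p))
  cat(sprintf("  treated: %d events / %.1f PY (%.2f per 100 PY)\n",
              x$arms$treated$events, x$arms$treated$person_years,
              x$arms$treated$rate_per_100py))
  cat(sprintf("  comparator: %d events / %.1f PY (%.2f per 100 PY)\n",
              x$arms$comparator$events, x$arms$comparator$person_years,
              x$arms$comparator$rate_per_100py))
  invisible(x)
}

#' Exposure to recommended secondary-prevention drugs (BASI)
#'
#' Flags, per episode, any dispensing of a beta-blocker, ASA, statin or
#' ACEI/ARB between the index date and the end of the initial exposure
#' period.
#'
#' @param db a `claims_db`
#' @param cohort cohort table (for index dates)
#' @param episodes exposure table from [derive_exposure()]
#' @return logical vector aligned with `episodes`
#' @export
basi_exposure <- function(db, cohort, episodes) {
  cs <- study_code_sets()
  basi_codes <- c(unname(cs$basi_atc), cs$apa_atc[["ASA"]])
  d <- db$dispensings[code %in% basi_codes]
  m <- merge(d, episodes[, .(patient_id, exposure_end_day)],
             by = "patient_id")
  m <- merge(m, cohort[, .(patient_id, index_date)], by = "patient_id")
  hit <- m[day >= index_date & day <= exposure_end_day,
           unique(patient_id)]
  episodes$patient_id %in% hit
}
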