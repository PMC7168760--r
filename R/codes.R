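## Reserved code vocabularies shared by the generator and the analysis
## stages. The diagnosis codes for the inclusion disease and the clinical
## endpoints follow the ICD-10 shapes used in French hospital-discharge
## summaries; drug codes for the study drugs follow ATC. Everything else is
## a synthetic vocabulary: downstream stages only rely on structure, never
## on real national code lists.

#' Reserved code sets used by the study definitions
#'
#' Returns the code sets that define the inclusion disease (acute coronary
#' syndrome, ACS), its index-diagnosis strata, the clinical endpoints
#' (ischemic/undefined stroke, major bleeding), revascularization procedures
#' (PCI/CABG), and the study antiplatelet drugs (ATC).
#'
#' @return named list of character vectors
#' @export
#' @examples
#' study_code_sets()$acs
study_code_sets <- function() {
  stemi <- c("I21.0", "I21.1", "I21.2", "I21.3", "I21.9")
  nstemi <- "I21.4"
  ua <- "I20.0"
  list(
    acs = c(ua, stemi, nstemi),
    ua = ua, stemi = stemi, nstemi = nstemi,
    stroke = c("I63.0", "I63.1", "I63.2", "I63.3", "I63.4", "I63.5",
               "I63.8", "I63.9", "I64"),
    bleeding = c("I60.0", "I60.9", "I61.0", "I61.9", "I62.9",
                 "K92.0", "K92.1", "K92.2", "R58"),
    pci_procedures = c("PCI001", "PCI002", "PCI003"),
    cabg_procedures = c("CABG01", "CABG02"),
    apa_atc = c(clopidogrel = "B01AC04", prasugrel = "B01AC22",
                ticagrelor = "B01AC24", ASA = "B01AC06"),
    antidiabetic_atc = c("A10B001", "A10B002", "A10B003"),
    basi_atc = c(beta_blocker = "C07AB02", statin = "C10AA05",
                 acei_arb = "C09AA02"),
    acs_ltd = "LTD13"
  )
}

#' Stratum map for ACS primary diagnosis codes
#'
#' @return named character vector mapping primary code to stratum
#' @export
acs_stratum_map <- function() {
  cs <- study_code_sets()
  c(setNames(rep("UA", length(cs$ua)), cs$ua),
    setNames(rep("STEMI", length(cs$stemi)), cs$stemi),
    setNames(rep("NSTEMI", length(cs$nstemi)), cs$nstemi))
}

#' Condition code maps for predefined comorbidity algorithms
#'
#' Each condition maps to the LTD codes, hospital diagnosis codes and/or ATC
#' drug codes that identify it in the claims tables. These synthetic maps
#' stand in for full national code lists; the identification logic
#' (LTD or diagnosis or dispensing-count rules) is the object of interest.
#'
#' @return named list; each element has `ltd`, `dx`, `atc` character vectors
#' @export
condition_code_maps <- function() {
  cs <- study_code_sets()
  list(
    mi              = list(ltd = "LTD13", dx = c("I25.2", cs$acs), atc = character()),
    diabetes        = list(ltd = "LTD08", dx = c("E11.9", "E14.9"),
                           atc = cs$antidiabetic_atc),
    diabetes_organ  = list(ltd = character(), dx = "E11.2", atc = character()),
    hypertension    = list(ltd = "LTD12", dx = "I10", atc = character()),
    chf             = list(ltd = "LTD05", dx = "I50.9", atc = character()),
    pvd             = list(ltd = character(), dx = "I73.9", atc = character()),
    cerebrovascular = list(ltd = "LTD01", dx = c("I69.3", cs$stroke), atc = character()),
    dementia        = list(ltd = "LTD15", dx = "G30.9", atc = character()),
    copd            = list(ltd = "LTD14", dx = "J44.9", atc = character()),
    connective      = list(ltd = character(), dx = "M35.9", atc = character()),
    ulcer           = list(ltd = character(), dx = "K27.9", atc = character()),
    liver_mild      = list(ltd = "LTD06", dx = "K76.0", atc = character()),
    liver_severe    = list(ltd = character(), dx = "K72.9", atc = character()),
    renal           = list(ltd = "LTD19", dx = "N18.9", atc = character()),
    hemiplegia      = list(ltd = character(), dx = "G81.9", atc = character()),
    cancer          = list(ltd = "LTD30", dx = "C50.9", atc = character()),
    metastatic      = list(ltd = character(), dx = "C79.9", atc = character()),
    hiv             = list(ltd = "LTD11", dx = "B24", atc = character()),
    bleeding_hx     = list(ltd = character(), dx = cs$bleeding, atc = character()),
    cad             = list(ltd = "LTD13", dx = "I25.1", atc = character()),
    pad             = list(ltd = character(), dx = "I70.2", atc = character()),
    stroke_hx       = list(ltd = "LTD01", dx = cs$stroke, atc = character())
  )
}

#' Default drug dictionary
#'
#' Maps dispensed drug codes to pack content (units per pack), defined daily
#' dose per unit, and study drug family. Codes absent from the dictionary are
#' treated as family "other" with the default pack content when
#' `strict = FALSE` in the exposure functions.
#'
#' @param extra_codes character vector of additional codes to register with
#'   default pack content and family "other"
#' @return `data.table` with columns code, units_per_pack, ddd_per_unit,
#'   family
#' @export
drug_dictionary <- function(extra_codes = character()) {
  cs <- study_code_sets()
  apa <- cs$apa_atc
  base <- data.table::data.table(
    code = unname(apa),
    units_per_pack = 30L,
    ddd_per_unit = 1,
    family = names(apa)
  )
  others <- unique(setdiff(extra_codes, base$code))
  if (length(others)) {
    base <- rbind(base, data.table::data.table(
      code = others, units_per_pack = 30L, ddd_per_unit = 1,
      family = "other"))
  }
  if (any(base$ddd_per_unit <= 0)) stop_config("ddd_per_unit must be > 0")
  base[]
}

## ---- synthetic code universe -------------------------------------------

make_codes <- function(prefix, n) {
  if (n <= 0) return(character())
  paste0(prefix, sprintf("%03d", seq_len(n)))
}

#' Build the synthetic code universe for the claims generator
#'
#' Latent patient states are materialized into blocks of proxy codes in each
#' claims dimension (diagnosis, drug, lab, procedure, visit specialty, LTD);
#' background codes carry no information about the latent states. Emission
#' probabilities per code are drawn once (under the caller's RNG state):
#' proxies fire with probability in `[fidelity["lo"], fidelity["hi"]]` when
#' the latent state is present and `[fidelity["bg_lo"], fidelity["bg_hi"]]`
#' otherwise; background codes fire with a code-specific prevalence.
#'
#' @param vocab_sizes named integer vector of background vocabulary sizes per
#'   dimension (diagnosis, drug, lab, procedure, visit, ltd)
#' @param proxy_per_latent named integer vector of proxy codes per latent per
#'   dimension
#' @param latents character vector of latent state names
#' @param fidelity named numeric vector lo/hi/bg_lo/bg_hi
#' @return `data.table` with columns dimension, code, role, latent, p_on,
#'   p_off
#' @keywords internal
build_code_universe <- function(vocab_sizes, proxy_per_latent, latents,
                                fidelity) {
  dims <- c("diagnosis", "drug", "lab", "procedure", "visit", "ltd")
  prefix <- list(
    diagnosis = c(cardiometabolic = "M", frailty = "S", background = "Z"),
    drug      = c(cardiometabolic = "ATCM", frailty = "ATCS", background = "ATCZ"),
    lab       = c(cardiometabolic = "LABM", frailty = "LABS", background = "LABZ"),
    procedure = c(cardiometabolic = "PRM", frailty = "PRS", background = "PRZ"),
    visit     = c(cardiometabolic = "SPM", frailty = "SPS", background = "SPZ"),
    ltd       = c(cardiometabolic = "LTDM", frailty = "LTDS", background = "LTDZ")
  )
  out <- list()
  for (d in dims) {
    for (l in latents) {
      n <- proxy_per_latent[[d]]
      codes <- make_codes(prefix[[d]][[l]], n)
      if (!length(codes)) next
      out[[paste(d, l)]] <- data.table::data.table(
        dimension = d, code = codes, role = "proxy", latent = l,
        p_on = runif(n, fidelity[["lo"]], fidelity[["hi"]]),
        p_off = runif(n, fidelity[["bg_lo"]], fidelity[["bg_hi"]])
      )
    }
    nb <- vocab_sizes[[d]]
    if (nb > 0) {
      ## a handful of common codes per dimension, the rest uncommon
      n_common <- min(5L, nb)
      prev <- c(runif(n_common, 0.3, 0.8),
                runif(nb - n_common, 0.005, 0.10))
      out[[paste(d, "bg")]] <- data.table::data.table(
        dimension = d, code = make_codes(prefix[[d]][["background"]], nb),
        role = "background", latent = NA_character_,
        p_on = prev, p_off = prev
      )
    }
  }
  data.table::rbindlist(out)
}
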