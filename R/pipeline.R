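## End-to-end orchestration: simulate (or load) the claims database, build
## the cohort, derive exposure, build covariates, generate and prioritize
## empirical covariates, fit the hdPS, match, compute balance, and compare
## incidence — under a single configuration and a single master seed fanned
## out to per-stage substreams.

#' Study configuration for the end-to-end pipeline
#'
#' @param n_patients patients in the simulated database
#' @param seed master seed; per-stage seeds are derived with
#'   [substream_seed()]
#' @param comparison length-2 character: treated drug, comparator drug
#' @param k number of empirical covariates selected into the score
#' @param top_n_codes most prevalent codes retained per dimension
#' @param endpoint endpoint used for prioritization and comparison
#' @param match_algorithm "greedy_nearest" or "optimal"
#' @param simulation optional [simulation_config()]; by default one is
#'   built from `n_patients` and the derived stage seed
#' @param output_dir optional directory: stage tables are written as CSV
#' @return object of class `study_config`
#' @export
study_config <- function(n_patients = 20000L, seed = 1L,
                         comparison = c("ticagrelor", "clopidogrel"),
                         k = 500L, top_n_codes = 200L,
                         endpoint = "primary_effectiveness",
                         match_algorithm = "greedy_nearest",
                         simulation = NULL,
                         output_dir = NULL) {
  known <- c("clopidogrel", "prasugrel", "ticagrelor")
  if (length(comparison) != 2L || !all(comparison %in% known) ||
      comparison[1] == comparison[2])
    stop_config("comparison must name two distinct drugs among: %s",
                paste(known, collapse = ", "))
  if (!endpoint %in% names(endpoint_definitions()))
    stop_config("unknown endpoint '%s'", endpoint)
  if (is.null(simulation))
    simulation <- simulation_config(n_patients = n_patients,
                                    seed = substream_seed(seed,
                                                          "simulate"))
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed), comparison = comparison,
                 k = as.integer(k), top_n_codes = as.integer(top_n_codes),
                 endpoint = endpoint, match_algorithm = match_algorithm,
                 simulation = simulation, output_dir = output_dir),
            class = "study_config")
}

#' Run the full matched-cohort study on synthetic claims
#'
#' Executes simulate, cohort selection, exposure derivation, covariate
#' construction, empirical-covariate generation, Bross prioritization,
#' propensity fitting, 1:1 caliper matching, balance diagnostics and
#' incidence comparison (crude, hdPS-adjusted and matched) for the
#' configured drug pair. The run is deterministic given the configuration.
#'
#' @param config a [study_config()]
#' @param db optional pre-built `claims_db` (skips simulation)
#' @return object of class `study_run`: all stage outputs plus a manifest
#'   of per-stage counts
#' @export
run_study <- function(config = study_config(), db = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(db)) db <- simulate_claims(config$simulation)

  sel <- select_cohort(db)
  cohort <- sel$cohort

  episodes <- derive_exposure(db, cohort)
  episodes <- merge(episodes,
                    cohort[, .(patient_id, index_date, stratum, gender,
                               age_years)],
                    by = "patient_id")

  ## analysis set: patients starting one of the compared drugs
  ana <- episodes[treatment %in% config$comparison]
  ana_cohort <- cohort[patient_id %in% ana$patient_id]
  data.table::setkey(ana, patient_id)
  ana <- ana[J(ana_cohort$patient_id)]
  treated <- ana$treatment == config$comparison[1]

  covs <- build_covariates(db, ana_cohort)
  forced <- forced_covariate_matrix(covs)

  emp <- generate_empirical_covariates(
    db, ana_cohort, hdps_dimensions(config$top_n_codes))

  times <- derive_event_times(db, ana, endpoint_definitions()[[
    config$endpoint]])
  times <- times[match(ana$patient_id, patient_id)]
  outcome <- times$event == 1L

  inv <- prioritize_covariates(emp, treated, outcome, k = config$k)
  sel_ids <- inv[selected == TRUE, covariate_id]
  model <- fit_hdps(forced, emp$matrix[, sel_ids, drop = FALSE], treated)

  match_in <- data.table::data.table(
    patient_id = ana$patient_id, score = model$score,
    age_years = ana$age_years, gender = ana$gender,
    stratum = ana$stratum)
  matched <- match_cohort(match_in, treated,
                          match_spec(algorithm = config$match_algorithm))

  model_X <- cbind(forced, emp$matrix[, sel_ids, drop = FALSE])
  rownames(model_X) <- as.character(ana$patient_id)
  balance <- balance_report(model_X, treated, matched = matched,
                            scores = model$score)

  basi <- basi_exposure(db, ana_cohort, ana)
  res <- list()
  res$crude <- compare_incidence(times$time, times$event, treated)
  adj <- data.frame(score = model$score,
                    female = as.numeric(ana$gender == "F"),
                    age = ana$age_years,
                    asa_index = as.numeric(ana$asa_at_index),
                    incident_or_naive = as.numeric(covs$incident_or_naive),
                    basi = as.numeric(basi))
  res$adjusted <- compare_incidence(times$time, times$event, treated,
                                    covariates = adj)
  midx <- match(c(matched$pairs$treated_id, matched$pairs$comparator_id),
                ana$patient_id)
  mpair <- rep(matched$pairs$pair_id, 2L)
  res$matched <- compare_incidence(
    times$time[midx], times$event[midx], treated[midx],
    covariates = adj[midx, c("asa_index", "incident_or_naive", "basi")],
    pair_id = mpair)
  ## conditional (within-pair) estimate: the recovery target in simulations
  res$matched_conditional <- tryCatch(
    compare_incidence(times$time[midx], times$event[midx], treated[midx],
                      pair_id = mpair, stratified = TRUE),
    error = function(e) NULL)

  manifest <- list(
    seed = config$seed, n_patients = nrow(db$patients),
    n_extracted = sel$flowchart$n_remaining[1],
    n_cohort = nrow(cohort), n_analysis = nrow(ana),
    n_treated = sum(treated), n_comparator = sum(!treated),
    n_candidate_covariates = nrow(inv),
    n_selected_covariates = length(sel_ids),
    n_model_columns = length(model$kept),
    n_pairs = nrow(matched$pairs),
    max_abs_smd_crude_pct = 100 * balance$summary$max_abs_d_crude,
    max_abs_smd_matched_pct = 100 * balance$summary$max_abs_d_matched,
    score_checksum = round(sum(model$score^2), 6))

  run <- list(config = config, db = db, flowchart = sel$flowchart,
              cohort = cohort, episodes = episodes, covariates = covs,
              empirical = emp, prioritization = inv, model = model,
              treated = treated, analysis = ana, matched = matched,
              balance = balance, times = times, results = res,
              manifest = manifest)
  class(run) <- "study_run"
  if (!is.null(config$output_dir)) write_study_run(run,
                                                   config$output_dir)
  run
}

#' @export
print.study_run <- function(x, ...) {
  m <- x$manifest
  cat("<study_run>", paste(x$config$comparison, collapse = " vs "), "\n")
  cat(sprintf("  cohort %d | analysis %d (%d vs %d) | pairs %d\n",
              m$n_cohort, m$n_analysis, m$n_treated, m$n_comparator,
              m$n_pairs))
  cat(sprintf("  max |SMD|: crude %.1f%% -> matched %.1f%%\n",
              m$max_abs_smd_crude_pct, m$max_abs_smd_matched_pct))
  cat(sprintf("  matched %s: ratio %.3f (95%% CI %.3f-%.3f)\n",
              x$results$matched$model, x$results$matched$estimate,
              x$results$matched$ci[1], x$results$matched$ci[2]))
  invisible(x)
}

#' Write the stage outputs of a study run as CSV tables
#'
#' @param run a `study_run`
#' @param directory target directory
#' @return the directory, invisibly
#' @export
write_study_run <- function(run, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, nm) data.table::fwrite(x, file.path(directory,
                                                        paste0(nm,
                                                               ".csv")))
  fw(run$flowchart, "flowchart")
  fw(run$cohort, "cohort")
  fw(run$episodes, "episodes")
  fw(run$covariates, "covariates")
  fw(run$prioritization, "covariate_inventory")
  fw(data.table::data.table(patient_id = run$analysis$patient_id,
                            treated = run$treated,
                            score = run$model$score), "scores")
  fw(run$matched$pairs, "pairs")
  fw(run$balance$table, "balance")
  jsonlite::write_json(run$manifest, file.path(directory,
                                               "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(directory)
}
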