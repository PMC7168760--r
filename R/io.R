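## Plain-text persistence for claims databases: one CSV per event table plus
## a JSON manifest with row counts and checksums. Round-tripping a database
## through disk reproduces it exactly (the generator's `meta` component is
## not persisted; it is provenance, not claims data).

claims_tables <- c("patients", "dispensings", "hospital_stays",
                   "stay_diagnoses", "stay_procedures", "ltd_registrations",
                   "visits", "lab_claims")

#' Write a claims database to a directory of CSV tables
#'
#' @param db a `claims_db`
#' @param directory target directory (created if absent)
#' @return the manifest, invisibly: a list with per-table row counts and
#'   MD5 checksums, also written to `manifest.json`
#' @export
write_claims_db <- function(db, directory) {
  stopifnot(inherits(db, "claims_db"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(directory, 2L) != 0L)
    stop_config("directory '%s' is not writable", directory)
  manifest <- list(tables = list())
  for (tb in claims_tables) {
    path <- file.path(directory, paste0(tb, ".csv"))
    data.table::fwrite(db[[tb]], path)
    manifest$tables[[tb]] <- list(
      rows = nrow(db[[tb]]),
      md5 = unname(tools::md5sum(path)))
  }
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

csv_schema <- list(
  patients = c(patient_id = "integer", gender = "character",
               birth_year = "integer", cmu_c = "logical",
               enrollment_day = "integer", observation_end = "integer",
               death_day = "integer"),
  dispensings = c(patient_id = "integer", day = "integer",
                  code = "character", packs = "integer",
                  units_per_pack = "integer", ddd_per_unit = "numeric"),
  hospital_stays = c(stay_id = "integer", patient_id = "integer",
                     admission_day = "integer", discharge_day = "integer",
                     primary_code = "character", intensive_care = "logical",
                     hospital_category = "character"),
  stay_diagnoses = c(stay_id = "integer", patient_id = "integer",
                     code = "character", type = "character"),
  stay_procedures = c(stay_id = "integer", patient_id = "integer",
                      code = "character"),
  ltd_registrations = c(patient_id = "integer", code = "character",
                        start_day = "integer", end_day = "integer"),
  visits = c(patient_id = "integer", day = "integer",
             specialty = "character"),
  lab_claims = c(patient_id = "integer", day = "integer",
                 code = "character")
)

#' Read a claims database written by [write_claims_db()]
#'
#' @param directory source directory
#' @return a `claims_db` (without generator metadata)
#' @export
read_claims_db <- function(directory) {
  db <- list()
  for (tb in claims_tables) {
    path <- file.path(directory, paste0(tb, ".csv"))
    if (!file.exists(path)) stop_config("missing table file '%s'", path)
    sch <- csv_schema[[tb]]
    t <- data.table::fread(path, colClasses = sch)
    if (!setequal(names(t), names(sch)))
      stop_config("table '%s' has unexpected columns", tb)
    data.table::setcolorder(t, names(sch))
    db[[tb]] <- t
  }
  db$meta <- list()
  class(db) <- "claims_db"
  validate_claims_db(db)
  db
}
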