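#' Analysis configuration
#'
#' Bundles the tunable parameters of the utilisation and off-label analysis.
#' Defaults reproduce the study conditions: statutory-insurance coverage of
#' 85% of the paediatric population (so the year-end population denominator
#' is multiplied by 0.85), rates per 10,000 children, a drug-inclusion
#' threshold of 0.1 per 10,000 in the final study year, study years
#' 2004-2008, and a maximum age of 18 completed years.
#'
#' @param coverage_fraction Fraction of the population covered by the claims
#'   database, in (0, 1]. Default 0.85.
#' @param ppr_scale Scale of period prevalence rates. Default 10,000.
#' @param inclusion_threshold_ppr Minimum PPR (at `ppr_scale`) in
#'   `inclusion_year` for a drug to enter the analysis; inclusive bound.
#'   Default 0.1.
#' @param inclusion_year Year whose PPR governs drug inclusion. Default: the
#'   final study year.
#' @param linkage_window How diagnoses are joined to prescriptions:
#'   `"same_quarter"` (claims diagnoses are documented per calendar quarter;
#'   default) or `"same_year"` (sensitivity analysis).
#' @param missing_diagnosis_policy Classification of prescriptions with no
#'   linked diagnosis: `"indeterminate"` (default; reported as its own
#'   column), `"on_label"`, or `"off_label_indication"`.
#' @param study_years Integer vector of calendar years. Default `2004:2008`.
#' @param max_age_years Maximum age in completed years. Default 18.
#' @param random_seed Integer seed recorded with every output.
#' @return An object of class `"analysis_config"` (a validated list).
#' @export
analysis_config <- function(coverage_fraction = 0.85,
                            ppr_scale = 10000,
                            inclusion_threshold_ppr = 0.1,
                            inclusion_year = NULL,
                            linkage_window = c("same_quarter", "same_year"),
                            missing_diagnosis_policy = c("indeterminate",
                                                         "on_label",
                                                         "off_label_indication"),
                            study_years = 2004:2008,
                            max_age_years = 18,
                            random_seed = 1L) {
  linkage_window <- match.arg(linkage_window)
  missing_diagnosis_policy <- match.arg(missing_diagnosis_policy)
  if (!is.numeric(coverage_fraction) || length(coverage_fraction) != 1 ||
      is.na(coverage_fraction) || coverage_fraction <= 0 ||
      coverage_fraction > 1) {
    stop_offlabelr("coverage_fraction must be a single number in (0, 1]",
                   class = "offlabelr_validation_error")
  }
  if (!is.numeric(ppr_scale) || ppr_scale <= 0) {
    stop_offlabelr("ppr_scale must be positive",
                   class = "offlabelr_validation_error")
  }
  if (!is.numeric(inclusion_threshold_ppr) || inclusion_threshold_ppr < 0) {
    stop_offlabelr("inclusion_threshold_ppr must be non-negative",
                   class = "offlabelr_validation_error")
  }
  study_years <- sort(as.integer(study_years))
  inclusion_year <- as.integer(inclusion_year %||% max(study_years))
  structure(
    list(
      coverage_fraction = coverage_fraction,
      ppr_scale = ppr_scale,
      inclusion_threshold_ppr = inclusion_threshold_ppr,
      inclusion_year = inclusion_year,
      linkage_window = linkage_window,
      missing_diagnosis_policy = missing_diagnosis_policy,
      study_years = study_years,
      max_age_years = as.integer(max_age_years),
      random_seed = as.integer(random_seed)
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}

#' Read a claims-style dataset
#'
#' Reads the three claims tables (patients, prescription events, diagnosis
#' events) from CSV, validates field formats and referential integrity, and
#' returns them as a `claims_dataset` list.
#'
#' Expected columns: `patients(patient_id, birth_date, gender)`,
#' `prescriptions(rx_id, patient_id, atc_code, dispense_date)`,
#' `diagnoses(patient_id, icd_code, year, quarter)`. Dates are ISO-8601;
#' diagnoses carry calendar year and quarter only, mirroring the quarterly
#' granularity of ambulatory claims coding.
#'
#' @param patients_path,prescriptions_path,diagnoses_path CSV file paths.
#' @return A list with tibbles `patients`, `prescriptions`, `diagnoses`,
#'   class `"claims_dataset"`.
#' @export
read_claims <- function(patients_path, prescriptions_path, diagnoses_path) {
  for (p in c(patients_path, prescriptions_path, diagnoses_path)) {
    if (!file.exists(p)) stop_offlabelr(sprintf("file not found: %s", p))
  }
  patients <- readr::read_csv(patients_path, show_col_types = FALSE,
                              col_types = readr::cols(
                                patient_id = readr::col_character(),
                                birth_date = readr::col_date(),
                                gender = readr::col_character()
                              ))
  prescriptions <- readr::read_csv(prescriptions_path, show_col_types = FALSE,
                                   col_types = readr::cols(
                                     rx_id = readr::col_character(),
                                     patient_id = readr::col_character(),
                                     atc_code = readr::col_character(),
                                     dispense_date = readr::col_date()
                                   ))
  diagnoses <- readr::read_csv(diagnoses_path, show_col_types = FALSE,
                               col_types = readr::cols(
                                 patient_id = readr::col_character(),
                                 icd_code = readr::col_character(),
                                 year = readr::col_integer(),
                                 quarter = readr::col_integer()
                               ))
  claims_dataset(patients, prescriptions, diagnoses)
}

#' Assemble and validate a claims dataset from in-memory tables
#'
#' @param patients,prescriptions,diagnoses Tibbles with the columns described
#'   in [read_claims()].
#' @return A validated `claims_dataset`.
#' @export
claims_dataset <- function(patients, prescriptions, diagnoses) {
  assert_columns(patients, c("patient_id", "birth_date", "gender"), "patients")
  assert_columns(prescriptions, c("rx_id", "patient_id", "atc_code",
                                  "dispense_date"), "prescriptions")
  assert_columns(diagnoses, c("patient_id", "icd_code", "year", "quarter"),
                 "diagnoses")
  if (anyDuplicated(patients$patient_id)) {
    dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
    stop_offlabelr(sprintf("duplicate patient_id: %s",
                           paste(utils::head(dup, 5), collapse = ", ")),
                   class = "offlabelr_validation_error")
  }
  if (anyDuplicated(prescriptions$rx_id)) {
    dup <- unique(prescriptions$rx_id[duplicated(prescriptions$rx_id)])
    stop_offlabelr(sprintf("duplicate rx_id: %s",
                           paste(utils::head(dup, 5), collapse = ", ")),
                   class = "offlabelr_validation_error")
  }
  if (any(is.na(patients$birth_date))) {
    stop_offlabelr("unparseable birth_date in patients",
                   class = "offlabelr_validation_error")
  }
  if (any(is.na(prescriptions$dispense_date))) {
    stop_offlabelr("unparseable dispense_date in prescriptions",
                   class = "offlabelr_validation_error")
  }
  bad_gender <- setdiff(unique(patients$gender), c("male", "female"))
  if (length(bad_gender) > 0) {
    stop_offlabelr(sprintf("gender must be male/female, found: %s",
                           paste(bad_gender, collapse = ", ")),
                   class = "offlabelr_validation_error")
  }
  if (nrow(diagnoses) > 0 && !all(diagnoses$quarter %in% 1:4)) {
    stop_offlabelr("diagnosis quarter must be in 1..4",
                   class = "offlabelr_validation_error")
  }
  orphan_rx <- setdiff(prescriptions$patient_id, patients$patient_id)
  if (length(orphan_rx) > 0) {
    ids <- prescriptions$rx_id[prescriptions$patient_id %in% orphan_rx]
    stop_offlabelr(
      sprintf("prescription(s) reference unknown patient_id: rx_id %s",
              paste(utils::head(ids, 5), collapse = ", ")),
      class = "offlabelr_validation_error"
    )
  }
  orphan_dx <- setdiff(diagnoses$patient_id, patients$patient_id)
  if (length(orphan_dx) > 0) {
    stop_offlabelr(
      sprintf("diagnosis rows reference unknown patient_id: %s",
              paste(utils::head(orphan_dx, 5), collapse = ", ")),
      class = "offlabelr_validation_error"
    )
  }
  structure(
    list(patients = as_tibble(patients),
         prescriptions = as_tibble(prescriptions),
         diagnoses = as_tibble(diagnoses)),
    class = "claims_dataset"
  )
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat(sprintf("<claims_dataset> %d patients, %d prescriptions, %d diagnoses\n",
              nrow(x$patients), nrow(x$prescriptions), nrow(x$diagnoses)))
  invisible(x)
}

#' Write a claims dataset to CSV tables
#'
#' Inverse of [read_claims()]: writes `patients.csv`, `prescriptions.csv`
#' and `diagnoses.csv` (ISO-8601 dates) into `dir`.
#'
#' @param dataset A `claims_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_claims <- function(dataset, dir) {
  stopifnot(inherits(dataset, "claims_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("patients.csv", "prescriptions.csv",
                            "diagnoses.csv"))
  readr::write_csv(dataset$patients, paths[1])
  readr::write_csv(dataset$prescriptions, paths[2])
  readr::write_csv(dataset$diagnoses, paths[3])
  invisible(paths)
}

#' Read a population-denominator table
#'
#' One row per (year, age in completed years, gender) holding the year-end
#' population count the prevalence denominators are built from.
#'
#' @param path CSV with columns `year, age_years, gender, count`.
#' @return A validated tibble.
#' @export
read_population <- function(path) {
  pop <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           year = readr::col_integer(),
                           age_years = readr::col_integer(),
                           gender = readr::col_character(),
                           count = readr::col_double()
                         ))
  validate_population(pop)
}

validate_population <- function(pop) {
  assert_columns(pop, c("year", "age_years", "gender", "count"), "population")
  key <- paste(pop$year, pop$age_years, pop$gender)
  if (anyDuplicated(key)) {
    stop_offlabelr("population table has duplicate (year, age, gender) rows",
                   class = "offlabelr_validation_error")
  }
  if (any(pop$count < 0)) {
    stop_offlabelr("population counts must be non-negative",
                   class = "offlabelr_validation_error")
  }
  as_tibble(pop)
}

#' Age in completed years
#'
#' Birthday-adjusted integer age: the number of whole years between
#' `birth_date` and `reference_date`.
#'
#' @param birth_date,reference_date `Date` vectors (recycled).
#' @return Integer vector of completed years.
#' @export
#' @examples
#' compute_age(as.Date("2000-06-01"), as.Date("2008-05-31")) # 7
#' compute_age(as.Date("2000-06-01"), as.Date("2008-06-01")) # 8
compute_age <- function(birth_date, reference_date) {
  if (any(reference_date < birth_date)) {
    stop_offlabelr("reference_date precedes birth_date")
  }
  b <- as.POSIXlt(birth_date)
  r <- as.POSIXlt(reference_date)
  age <- (r$year - b$year) -
    ((r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday))
  as.integer(age)
}

# calendar quarter of a Date
quarter_of <- function(date) {
  (as.integer(format(date, "%m")) + 2L) %/% 3L
}

#' Restrict a claims dataset to the study population
#'
#' Keeps prescriptions dispensed within the study years to patients aged at
#' most `max_age_years` (completed years at the dispense date), then keeps
#' the patients with at least one retained prescription and all their
#' diagnoses. Idempotent.
#'
#' @param dataset A `claims_dataset`.
#' @param config An [analysis_config()].
#' @return A filtered `claims_dataset`.
#' @export
filter_study_population <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "claims_dataset"))
  rx <- dataset$prescriptions
  if (nrow(rx) > 0) {
    rx <- dplyr::left_join(
      rx, dplyr::select(dataset$patients, "patient_id", "birth_date"),
      by = "patient_id"
    )
    year <- as.integer(format(rx$dispense_date, "%Y"))
    age <- compute_age(rx$birth_date, rx$dispense_date)
    keep <- year %in% config$study_years & age <= config$max_age_years
    rx <- dplyr::select(rx[keep, , drop = FALSE], -"birth_date")
  }
  kept_patients <- dataset$patients[
    dataset$patients$patient_id %in% rx$patient_id, , drop = FALSE]
  kept_dx <- dataset$diagnoses[
    dataset$diagnoses$patient_id %in% rx$patient_id, , drop = FALSE]
  claims_dataset(kept_patients, rx, kept_dx)
}

#' Link diagnoses to prescriptions
#'
#' Joins each prescription to the diagnosis codes documented for the same
#' patient in the dispense quarter (`"same_quarter"`, the native granularity
#' of ambulatory claims coding) or the dispense year (`"same_year"`). The
#' same-year set is always a superset of the same-quarter set.
#'
#' @param prescriptions Tibble of prescription events.
#' @param diagnoses Tibble of diagnosis events.
#' @param window `"same_quarter"` or `"same_year"`.
#' @return Tibble `(rx_id, icd_code)` with one row per linked (prescription,
#'   distinct code) pair; prescriptions with no linked diagnosis are absent.
#' @export
link_diagnoses <- function(prescriptions, diagnoses,
                           window = c("same_quarter", "same_year")) {
  window <- match.arg(window)
  if (nrow(prescriptions) == 0 || nrow(diagnoses) == 0) {
    return(tibble(rx_id = character(0), icd_code = character(0)))
  }
  rx <- dplyr::mutate(
    prescriptions,
    year = as.integer(format(.data$dispense_date, "%Y")),
    quarter = quarter_of(.data$dispense_date)
  )
  keys <- if (window == "same_quarter") {
    c("patient_id", "year", "quarter")
  } else {
    c("patient_id", "year")
  }
  linked <- dplyr::inner_join(
    dplyr::select(rx, "rx_id", dplyr::all_of(keys)),
    dplyr::select(diagnoses, dplyr::all_of(c(keys, "icd_code"))),
    by = keys, relationship = "many-to-many"
  )
  dplyr::distinct(linked, .data$rx_id, .data$icd_code)
}
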