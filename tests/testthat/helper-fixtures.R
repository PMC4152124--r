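# Shared fixtures: a small hand-built label KB, compact claims builders, and
# a deliberately naive per-prescription re-implementation of the off-label
# rules used as an independent oracle.

test_kb <- function() {
  tibble::tibble(
    atc_code = c("R03AC02", "R03AC04", "R03BB04"),
    compound_name = c("broad bronchodilator", "age-restricted bronchodilator",
                      "adult-only anticholinergic"),
    compound_class = c("inhaled_saba", "inhaled_saba", "lama"),
    min_age_years = c(0L, 4L, 18L),
    indication_prefixes = c("J43;J44;J45;J46", "J43;J44;J45;J46", "J44"),
    source_year = c(2008L, 2008L, 2008L),
    indication_codes = list(c("J43", "J44", "J45", "J46"),
                            c("J43", "J44", "J45", "J46"), "J44")
  )
}

make_patients <- function(n, birth_years = 2000, gender = "male") {
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    birth_date = as.Date(sprintf("%d-06-15", rep_len(birth_years, n))),
    gender = rep_len(gender, n)
  )
}

make_rx <- function(patient_id, atc_code, dispense_date) {
  tibble::tibble(
    rx_id = sprintf("RX%03d", seq_along(patient_id)),
    patient_id = patient_id,
    atc_code = atc_code,
    dispense_date = as.Date(dispense_date)
  )
}

make_dx <- function(patient_id, icd_code, year, quarter) {
  tibble::tibble(patient_id = patient_id, icd_code = icd_code,
                 year = as.integer(year), quarter = as.integer(quarter))
}

# Random dataset generator for oracle-equivalence tests: arbitrary ages,
# drugs, diagnosis codes (some off-label, some missing), built directly
# rather than through the package's scenario machinery.
random_claims <- function(n_rx, kb = test_kb(), year = 2008) {
  n_pat <- max(2L, ceiling(n_rx / 10))
  patients <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n_pat)),
    birth_date = as.Date(sprintf("%d-%02d-%02d",
                                 sample(1989:year, n_pat, replace = TRUE),
                                 sample(1:12, n_pat, replace = TRUE),
                                 sample(1:28, n_pat, replace = TRUE))),
    gender = sample(c("male", "female"), n_pat, replace = TRUE)
  )
  rx <- tibble::tibble(
    rx_id = sprintf("RX%05d", seq_len(n_rx)),
    patient_id = sample(patients$patient_id, n_rx, replace = TRUE),
    atc_code = sample(kb$atc_code, n_rx, replace = TRUE),
    dispense_date = as.Date(sprintf("%d-%02d-%02d", year,
                                    sample(1:12, n_rx, replace = TRUE),
                                    sample(1:28, n_rx, replace = TRUE)))
  )
  # only dispense after birth
  bd <- patients$birth_date[match(rx$patient_id, patients$patient_id)]
  rx <- rx[rx$dispense_date >= bd, , drop = FALSE]
  rx$rx_id <- sprintf("RX%05d", seq_len(nrow(rx)))
  code_pool <- c("J45.9", "J45.0", "J44.9", "J20.9", "J06.9", "J40",
                 "J35.1", "K52.9", "j459")
  n_dx <- rpois(1, nrow(rx) * 0.8)
  diagnoses <- tibble::tibble(
    patient_id = sample(patients$patient_id, n_dx, replace = TRUE),
    icd_code = sample(code_pool, n_dx, replace = TRUE),
    year = rep(as.integer(year), n_dx),
    quarter = sample(1:4, n_dx, replace = TRUE)
  )
  claims_dataset(patients, rx, diagnoses)
}

# --- independent oracle -----------------------------------------------------
# One prescription at a time, plain loops, own code normalization and prefix
# test; shares no code path with classify_claims().

oracle_norm <- function(x) gsub("\\.", "", toupper(x))

oracle_match <- function(code, prefixes) {
  code <- oracle_norm(code)
  if (!grepl("^[A-Z][0-9][0-9]", code)) return(FALSE)
  for (p in oracle_norm(prefixes)) {
    if (substr(code, 1, nchar(p)) == p) return(TRUE)
  }
  FALSE
}

oracle_age <- function(birth, ref) {
  a <- as.integer(format(ref, "%Y")) - as.integer(format(birth, "%Y"))
  birthday <- as.Date(sprintf("%04d-%s", as.integer(format(ref, "%Y")),
                              format(birth, "%m-%d")))
  if (is.na(birthday)) {  # Feb 29 in a non-leap year: birthday is Mar 1
    birthday <- as.Date(sprintf("%04d-03-01", as.integer(format(ref, "%Y"))))
  }
  if (ref < birthday) a <- a - 1L
  a
}

oracle_classify_dataset <- function(dataset, kb, config) {
  statuses <- character(nrow(dataset$prescriptions))
  for (i in seq_len(nrow(dataset$prescriptions))) {
    rx <- dataset$prescriptions[i, ]
    pat <- dataset$patients[dataset$patients$patient_id == rx$patient_id, ]
    krows <- kb[kb$atc_code == rx$atc_code, ]
    min_age <- min(krows$min_age_years)
    prefixes <- unique(unlist(krows$indication_codes))
    age <- oracle_age(pat$birth_date, rx$dispense_date)
    ry <- as.integer(format(rx$dispense_date, "%Y"))
    rq <- (as.integer(format(rx$dispense_date, "%m")) - 1) %/% 3 + 1
    codes <- character(0)
    for (j in seq_len(nrow(dataset$diagnoses))) {
      dx <- dataset$diagnoses[j, ]
      same <- dx$patient_id == rx$patient_id && dx$year == ry &&
        (config$linkage_window == "same_year" || dx$quarter == rq)
      if (same) codes <- c(codes, dx$icd_code)
    }
    codes <- unique(codes)
    age_ok <- age >= min_age
    if (length(codes) == 0) {
      if (config$missing_diagnosis_policy == "indeterminate") {
        statuses[i] <- "INDETERMINATE"
        next
      }
      ind_ok <- config$missing_diagnosis_policy == "on_label"
    } else {
      ind_ok <- FALSE
      for (cd in codes) if (oracle_match(cd, prefixes)) ind_ok <- TRUE
    }
    statuses[i] <- if (age_ok && ind_ok) "ON_LABEL"
    else if (!age_ok && ind_ok) "OFF_AGE"
    else if (age_ok && !ind_ok) "OFF_INDICATION"
    else "OFF_AGE_AND_INDICATION"
  }
  statuses
}

oracle_tally <- function(atc, statuses) {
  out <- list()
  for (a in sort(unique(atc))) {
    s <- statuses[atc == a]
    out[[a]] <- c(
      n_all = length(s),
      n_age_only = sum(s == "OFF_AGE"),
      n_indication_only = sum(s == "OFF_INDICATION"),
      n_age_and_indication = sum(s == "OFF_AGE_AND_INDICATION"),
      n_indeterminate = sum(s == "INDETERMINATE")
    )
  }
  out
}
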