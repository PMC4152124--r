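#' Simulation scenario for synthetic claims data
#'
#' Defines a claims-database emulation with known ground truth: a paediatric
#' population (ages 0-18, configurable age weights and gender split) and,
#' per drug, an annual prescription rate per child (Poisson counts per
#' patient-year), a diagnosis mixture over ICD-10 codes, and a probability
#' that a prescription has no documented diagnosis. The generator mirrors
#' the structure of a German statutory-insurance ambulatory claims database:
#' dispense-dated prescriptions, quarter-resolution diagnoses, and a
#' year-end population denominator covering a fixed insured share.
#'
#' @param n_patients Number of children to simulate.
#' @param years Calendar years covered (default 2004:2008). A patient's age
#'   is sampled for the first year and advances with the calendar.
#' @param age_weights Sampling weights for completed age 0-18 at the end of
#'   the first year (length 19; default uniform).
#' @param p_male Proportion male (default 0.512, the usual paediatric sex
#'   ratio).
#' @param drugs Tibble with one row per simulated drug: `atc_code`,
#'   `annual_rx_rate` (expected prescriptions per child-year), `dx_mixture`
#'   (list-column of tibbles `icd_code, prob`), `p_missing_dx`. Per drug,
#'   mixture probabilities + `p_missing_dx` must sum to 1.
#' @param p_second_dx Probability that a prescription generates a second,
#'   independent diagnosis draw from the mixture (exercises multiple
#'   counting; default 0).
#' @param seed Master integer seed; per-stage child seeds are derived by
#'   fixed offsets.
#' @return A validated list of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(n_patients = 20000,
                                years = 2004:2008,
                                age_weights = rep(1, 19),
                                p_male = 0.512,
                                drugs = default_scenario_drugs(),
                                p_second_dx = 0,
                                seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop_offlabelr("n_patients must be a positive integer",
                   class = "offlabelr_validation_error")
  }
  if (length(age_weights) != 19 || any(age_weights < 0) ||
      sum(age_weights) <= 0) {
    stop_offlabelr("age_weights must be 19 non-negative weights (ages 0-18)",
                   class = "offlabelr_validation_error")
  }
  if (p_male < 0 || p_male > 1) {
    stop_offlabelr("p_male must be in [0, 1]",
                   class = "offlabelr_validation_error")
  }
  assert_columns(drugs, c("atc_code", "annual_rx_rate", "dx_mixture",
                          "p_missing_dx"), "drugs")
  if (any(!is.finite(drugs$annual_rx_rate)) || any(drugs$annual_rx_rate < 0)) {
    stop_offlabelr("annual_rx_rate must be finite and non-negative",
                   class = "offlabelr_validation_error")
  }
  for (i in seq_len(nrow(drugs))) {
    mix <- drugs$dx_mixture[[i]]
    assert_columns(mix, c("icd_code", "prob"),
                   sprintf("dx_mixture for %s", drugs$atc_code[i]))
    total <- sum(mix$prob) + drugs$p_missing_dx[i]
    if (abs(total - 1) > 1e-8) {
      stop_offlabelr(
        sprintf("dx_mixture probabilities + p_missing_dx must sum to 1 for %s (got %.6f)",
                drugs$atc_code[i], total),
        class = "offlabelr_validation_error"
      )
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), years = sort(as.integer(years)),
         age_weights = age_weights, p_male = p_male,
         drugs = as_tibble(drugs), p_second_dx = p_second_dx,
         seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

#' Default simulated drug panel
#'
#' Four drugs spanning the off-label rule space: an inhaled salbutamol
#' analogue (no age restriction, broad obstructive-disease indications), a
#' fenoterol analogue (minimum age 4), a tiotropium analogue (minimum age
#' 18, COPD only), and an oral clenbuterol/ambroxol-type fixed combination
#' (no age restriction, indications including acute bronchitis). Mixtures
#' blend on-label codes (J45 asthma, J44 COPD, J20 acute bronchitis where
#' approved) with the off-label codes dominating real prescribing (J20 acute
#' bronchitis, J06 acute upper respiratory infection). Annual rates are of
#' the magnitude implied by prevalence in the hundreds per 10,000 children.
#'
#' @return Tibble usable as the `drugs` argument of
#'   [simulation_scenario()].
#' @export
default_scenario_drugs <- function() {
  tibble(
    atc_code = c("R03AC02", "R03AC04", "R03BB04", "R03CC63"),
    annual_rx_rate = c(0.08, 0.012, 0.001, 0.07),
    dx_mixture = list(
      tibble(icd_code = c("J45.9", "J20.9", "J06.9"),
             prob = c(0.45, 0.25, 0.20)),
      tibble(icd_code = c("J45.9", "J20.9", "J30.1"),
             prob = c(0.55, 0.20, 0.15)),
      tibble(icd_code = c("J44.9", "J45.9"),
             prob = c(0.30, 0.50)),
      tibble(icd_code = c("J20.9", "J06.9", "J45.9"),
             prob = c(0.35, 0.35, 0.20))
    ),
    p_missing_dx = c(0.10, 0.10, 0.20, 0.10)
  )
}

#' Generate the synthetic study population
#'
#' Samples patients i.i.d. from the scenario's age and gender distribution
#' and derives the matching year-end population table: for every study year,
#' realized counts per (age 0-18, gender) divided by `coverage_fraction` and
#' rounded, so that prevalence denominators are internally consistent with
#' the simulated insured population.
#'
#' @param scenario A [simulation_scenario()].
#' @param coverage_fraction Insured share of the total population (default
#'   0.85), matching the analysis configuration used downstream.
#' @return List with `patients` (tibble `patient_id, birth_date, gender`)
#'   and `population` (tibble `year, age_years, gender, count`).
#' @export
generate_population <- function(scenario, coverage_fraction = 0.85) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_patients
  first_year <- scenario$years[1]
  age0 <- sample(0:18, n, replace = TRUE, prob = scenario$age_weights)
  birth_year <- first_year - age0
  # day-of-year uniform within the birth year; age at Dec 31 of first_year
  # equals the sampled age regardless of the day
  n_days <- ifelse(format(as.Date(sprintf("%d-12-31", birth_year)), "%j") == "366",
                   366L, 365L)
  doy <- floor(stats::runif(n) * n_days) + 1
  birth_date <- as.Date(sprintf("%d-01-01", birth_year)) + (doy - 1)
  gender <- ifelse(stats::runif(n) < scenario$p_male, "male", "female")
  patients <- tibble(
    patient_id = sprintf("P%07d", seq_len(n)),
    birth_date = birth_date,
    gender = gender
  )
  grid <- tidyr::expand_grid(
    year = scenario$years, age_years = 0:18,
    gender = c("male", "female")
  )
  realized <- dplyr::count(
    tibble(year = rep(scenario$years, each = n),
           age_years = rep(scenario$years, each = n) - rep(birth_year, length(scenario$years)),
           gender = rep(gender, length(scenario$years))),
    .data$year, .data$age_years, .data$gender, name = "insured"
  )
  population <- dplyr::left_join(grid, realized,
                                 by = c("year", "age_years", "gender"))
  population$insured[is.na(population$insured)] <- 0L
  population$count <- round(population$insured / coverage_fraction)
  population$insured <- NULL
  list(patients = patients, population = as_tibble(population))
}

#' Generate synthetic prescription and diagnosis events
#'
#' For each patient-year and drug, draws a Poisson number of prescriptions
#' at the drug's annual rate; each prescription gets a uniform dispense date
#' within the year (never before birth) and, with probability
#' `1 - p_missing_dx`, one diagnosis drawn from the drug's mixture and
#' documented in the dispense quarter. With probability `p_second_dx` a
#' second independent diagnosis is drawn. The component that fired is stored
#' in a sidecar truth table keyed by `rx_id`.
#'
#' @param scenario A [simulation_scenario()].
#' @param patients Patient tibble from [generate_population()].
#' @return List with tibbles `prescriptions`, `diagnoses`, and `truth`
#'   (`rx_id, patient_id, atc_code, year, quarter, true_icd, missing_dx,
#'   second_icd`).
#' @export
generate_claims <- function(scenario, patients) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed + 1L)
  grid <- tidyr::expand_grid(
    patient_idx = seq_len(nrow(patients)),
    year = scenario$years,
    drug_idx = seq_len(nrow(scenario$drugs))
  )
  rate <- scenario$drugs$annual_rx_rate[grid$drug_idx]
  n_rx <- stats::rpois(nrow(grid), rate)
  grid <- grid[rep(seq_len(nrow(grid)), n_rx), , drop = FALSE]
  n <- nrow(grid)
  if (n == 0) {
    empty_truth <- tibble(rx_id = character(0), patient_id = character(0),
                          atc_code = character(0), year = integer(0),
                          quarter = integer(0), true_icd = character(0),
                          missing_dx = logical(0), second_icd = character(0))
    return(list(
      prescriptions = tibble(rx_id = character(0), patient_id = character(0),
                             atc_code = character(0),
                             dispense_date = as.Date(character(0))),
      diagnoses = tibble(patient_id = character(0), icd_code = character(0),
                         year = integer(0), quarter = integer(0)),
      truth = empty_truth
    ))
  }
  birth <- patients$birth_date[grid$patient_idx]
  year_start <- as.Date(sprintf("%d-01-01", grid$year))
  year_days <- as.integer(as.Date(sprintf("%d-12-31", grid$year)) - year_start)
  offset <- floor(stats::runif(n) * (year_days + 1))
  dispense <- year_start + offset
  dispense <- pmax(dispense, birth)  # infants: never dispense before birth
  drugs <- scenario$drugs

  draw_component <- function(drug_idx) {
    # returns an ICD code per row, or NA for the missing-diagnosis component
    out <- rep(NA_character_, length(drug_idx))
    u <- stats::runif(length(drug_idx))
    for (d in unique(drug_idx)) {
      idx <- which(drug_idx == d)
      mix <- drugs$dx_mixture[[d]]
      probs <- c(mix$prob, drugs$p_missing_dx[d])
      codes <- c(mix$icd_code, NA_character_)
      comp <- findInterval(u[idx], cumsum(probs), left.open = TRUE) + 1L
      out[idx] <- codes[comp]
    }
    out
  }

  true_icd <- draw_component(grid$drug_idx)
  second_icd <- rep(NA_character_, n)
  if (scenario$p_second_dx > 0) {
    has_second <- stats::runif(n) < scenario$p_second_dx
    if (any(has_second)) {
      second_icd[has_second] <- draw_component(grid$drug_idx[has_second])
    }
  }

  prescriptions <- tibble(
    rx_id = sprintf("RX%08d", seq_len(n)),
    patient_id = patients$patient_id[grid$patient_idx],
    atc_code = drugs$atc_code[grid$drug_idx],
    dispense_date = dispense
  )
  truth <- tibble(
    rx_id = prescriptions$rx_id,
    patient_id = prescriptions$patient_id,
    atc_code = prescriptions$atc_code,
    year = grid$year,
    quarter = quarter_of(dispense),
    true_icd = true_icd,
    missing_dx = is.na(true_icd),
    second_icd = second_icd
  )
  dx_rows <- dplyr::bind_rows(
    tibble(patient_id = truth$patient_id, icd_code = truth$true_icd,
           year = truth$year, quarter = truth$quarter),
    tibble(patient_id = truth$patient_id, icd_code = truth$second_icd,
           year = truth$year, quarter = truth$quarter)
  )
  diagnoses <- dx_rows[!is.na(dx_rows$icd_code), , drop = FALSE]
  list(prescriptions = prescriptions, diagnoses = as_tibble(diagnoses),
       truth = truth)
}

#' Generate a complete synthetic claims dataset
#'
#' Convenience wrapper running [generate_population()] and
#' [generate_claims()] and assembling a validated [claims_dataset()].
#'
#' @inheritParams generate_population
#' @return List with `dataset` (a `claims_dataset`), `population`, `truth`,
#'   and the `scenario` echo.
#' @export
generate_claims_dataset <- function(scenario, coverage_fraction = 0.85) {
  pop <- generate_population(scenario, coverage_fraction)
  ev <- generate_claims(scenario, pop$patients)
  list(
    dataset = claims_dataset(pop$patients, ev$prescriptions, ev$diagnoses),
    population = pop$population,
    truth = ev$truth,
    scenario = scenario
  )
}

#' Write a synthetic dataset to disk
#'
#' Writes the four analysis tables, the ground-truth sidecar, and a YAML
#' echo of the scenario into `dir`.
#'
#' @param generated Output of [generate_claims_dataset()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_claims(generated$dataset, dir)
  pop_path <- file.path(dir, "population.csv")
  truth_path <- file.path(dir, "truth.csv")
  scen_path <- file.path(dir, "scenario.yaml")
  readr::write_csv(generated$population, pop_path)
  readr::write_csv(generated$truth, truth_path)
  scen <- generated$scenario
  echo <- list(
    n_patients = scen$n_patients, years = scen$years,
    age_weights = scen$age_weights, p_male = scen$p_male,
    p_second_dx = scen$p_second_dx, seed = scen$seed,
    drugs = lapply(seq_len(nrow(scen$drugs)), function(i) list(
      atc_code = scen$drugs$atc_code[i],
      annual_rx_rate = scen$drugs$annual_rx_rate[i],
      p_missing_dx = scen$drugs$p_missing_dx[i],
      dx_mixture = stats::setNames(as.list(scen$drugs$dx_mixture[[i]]$prob),
                                   scen$drugs$dx_mixture[[i]]$icd_code)
    ))
  )
  yaml::write_yaml(echo, scen_path)
  invisible(c(paths, pop_path, truth_path, scen_path))
}
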