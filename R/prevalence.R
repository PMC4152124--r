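#' Annual period prevalence rates
#'
#' The period prevalence rate (PPR) of a drug in a year is the number of
#' distinct children with at least one prescription of that drug during the
#' year (numerator) divided by the year-end population, corrected for the
#' insured share of the population (denominator multiplied by
#' `coverage_fraction`), and scaled per `ppr_scale` (default 10,000)
#' children. Stratification by one-year age group and gender uses age in
#' completed years on December 31 of the analysis year, matching the
#' year-end denominator; patients older than `max_age_years` at year end
#' are outside the prevalence population.
#'
#' @param dataset A `claims_dataset` (after [filter_study_population()]).
#' @param population Population table (`year, age_years, gender, count`).
#' @param config An [analysis_config()].
#' @param atc_codes Drugs to evaluate (default: all in the dataset).
#' @param years Years to evaluate (default: the config's study years
#'   present in the data).
#' @param strata `"total"`, `"age"`, `"gender"`, or `"age_gender"`.
#' @return Tibble of PPR rows: `atc_code, year, age_years, gender, n_users,
#'   population, corrected_denominator, ppr` (stratum columns hold `"ALL"`
#'   where unstratified).
#' @export
period_prevalence <- function(dataset, population, config = analysis_config(),
                              atc_codes = NULL, years = NULL,
                              strata = c("total", "age", "gender",
                                         "age_gender")) {
  strata <- match.arg(strata)
  stopifnot(inherits(dataset, "claims_dataset"))
  population <- validate_population(population)
  atc_codes <- atc_codes %||% sort(unique(dataset$prescriptions$atc_code))
  years <- as.integer(years %||% intersect(
    config$study_years,
    unique(as.integer(format(dataset$prescriptions$dispense_date, "%Y")))
  ))

  rx <- dplyr::left_join(
    dataset$prescriptions,
    dplyr::select(dataset$patients, "patient_id", "birth_date", "gender"),
    by = "patient_id"
  )
  rx$year <- as.integer(format(rx$dispense_date, "%Y"))
  rx <- rx[rx$atc_code %in% atc_codes & rx$year %in% years, , drop = FALSE]
  # stratum age: completed years at Dec 31 of the analysis year
  if (nrow(rx) > 0) {
    rx$age_years <- compute_age(rx$birth_date,
                                as.Date(sprintf("%d-12-31", rx$year)))
    rx <- rx[rx$age_years <= config$max_age_years, , drop = FALSE]
  } else {
    rx$age_years <- integer(0)
  }
  users <- dplyr::distinct(rx, .data$atc_code, .data$year, .data$patient_id,
                           .data$age_years, .data$gender)

  # required population strata must exist for every requested year
  need <- tidyr::expand_grid(year = years, age_years = 0:config$max_age_years,
                             gender = c("male", "female"))
  have <- dplyr::semi_join(need, population,
                           by = c("year", "age_years", "gender"))
  if (nrow(have) < nrow(need)) {
    miss <- dplyr::anti_join(need, population,
                             by = c("year", "age_years", "gender"))
    stop_offlabelr(
      sprintf("population table lacks stratum rows, e.g. (year %d, age %d, %s)",
              miss$year[1], miss$age_years[1], miss$gender[1]),
      class = "offlabelr_validation_error"
    )
  }
  pop <- population[population$year %in% years &
                      population$age_years <= config$max_age_years, ,
                    drop = FALSE]

  group_cols <- switch(strata,
                       total = character(0),
                       age = "age_years",
                       gender = "gender",
                       age_gender = c("age_years", "gender"))
  pop_strat <- dplyr::summarise(
    dplyr::group_by(pop, dplyr::across(dplyr::all_of(c("year", group_cols)))),
    population = sum(.data$count), .groups = "drop"
  )
  grid <- tidyr::expand_grid(atc_code = atc_codes, pop_strat)
  user_counts <- dplyr::count(
    users, dplyr::across(dplyr::all_of(c("atc_code", "year", group_cols))),
    name = "n_users"
  )
  out <- dplyr::left_join(grid, user_counts,
                          by = c("atc_code", "year", group_cols))
  out$n_users[is.na(out$n_users)] <- 0L
  out$corrected_denominator <- out$population * config$coverage_fraction
  if (any(out$n_users > 0 & out$corrected_denominator == 0)) {
    bad <- out[out$n_users > 0 & out$corrected_denominator == 0, ][1, ]
    stop_offlabelr(
      sprintf("zero population denominator with %d users (drug %s, year %d)",
              bad$n_users, bad$atc_code, bad$year),
      class = "offlabelr_validation_error"
    )
  }
  out$ppr <- ifelse(out$n_users == 0, 0,
                    config$ppr_scale * out$n_users / out$corrected_denominator)
  if (!"age_years" %in% names(out)) out$age_years <- "ALL"
  if (!"gender" %in% names(out)) out$gender <- "ALL"
  dplyr::select(out, "atc_code", "year", "age_years", "gender", "n_users",
                "population", "corrected_denominator", "ppr")
}

#' PPR change between two years
#'
#' Absolute change on the rate scale, relative change in percent, and fold
#' change; the latter two are NA (flagged) when the baseline rate is zero.
#'
#' @param ppr_a Baseline PPR (vectorised).
#' @param ppr_b Comparison PPR.
#' @return Tibble `ppr_a, ppr_b, absolute_change, relative_change_pct,
#'   fold_change, not_applicable`.
#' @export
#' @examples
#' ppr_change(378, 527)  # +149 per 10,000
ppr_change <- function(ppr_a, ppr_b) {
  if (any(ppr_a < 0) || any(ppr_b < 0)) {
    stop_offlabelr("PPRs must be non-negative")
  }
  zero <- ppr_a == 0
  tibble(
    ppr_a = ppr_a, ppr_b = ppr_b,
    absolute_change = ppr_b - ppr_a,
    relative_change_pct = ifelse(zero, NA_real_, 100 * (ppr_b - ppr_a) / ppr_a),
    fold_change = ifelse(zero, NA_real_, ppr_b / ppr_a),
    not_applicable = zero
  )
}

#' Drug inclusion filter
#'
#' Keeps the drugs whose unstratified PPR in the inclusion year reaches the
#' configured threshold (default: at least 0.1 per 10,000 children in the
#' final study year; the bound is inclusive).
#'
#' @param ppr_rows PPR rows from [period_prevalence()] (total stratum).
#' @param config An [analysis_config()].
#' @return Character vector of retained ATC codes.
#' @export
drug_inclusion_filter <- function(ppr_rows, config = analysis_config()) {
  rows <- ppr_rows[ppr_rows$year == config$inclusion_year &
                     ppr_rows$age_years == "ALL" &
                     ppr_rows$gender == "ALL", , drop = FALSE]
  sort(unique(rows$atc_code[rows$ppr >= config$inclusion_threshold_ppr]))
}
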