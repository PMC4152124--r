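small_scenario <- function(...) {
  simulation_scenario(n_patients = 2000, years = 2008, seed = 42, ...)
}

test_that("generation is fully deterministic under a fixed seed", {
  sc <- small_scenario()
  a <- generate_claims_dataset(sc)
  b <- generate_claims_dataset(sc)
  expect_identical(a$dataset$patients, b$dataset$patients)
  expect_identical(a$dataset$prescriptions, b$dataset$prescriptions)
  expect_identical(a$dataset$diagnoses, b$dataset$diagnoses)
  expect_identical(a$truth, b$truth)
  expect_identical(a$population, b$population)
})

test_that("gender split and age distribution boundaries are honoured", {
  all_male <- generate_population(simulation_scenario(
    n_patients = 500, years = 2008, p_male = 1, seed = 1))
  expect_true(all(all_male$patients$gender == "male"))
  only_age5 <- generate_population(simulation_scenario(
    n_patients = 500, years = 2008,
    age_weights = replace(rep(0, 19), 6, 1), seed = 1))
  expect_true(all(compute_age(only_age5$patients$birth_date,
                              as.Date("2008-12-31")) == 5L))
})

test_that("uniform age sampling puts each one-year stratum near n/19", {
  sc <- simulation_scenario(n_patients = 10000, years = 2008, seed = 1)
  pop <- generate_population(sc)
  ages <- compute_age(pop$patients$birth_date, as.Date("2008-12-31"))
  counts <- table(factor(ages, levels = 0:18))
  p <- 1 / 19
  se <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) <= 3 * se))
})

test_that("population table equals realized counts scaled by coverage", {
  sc <- small_scenario()
  pop <- generate_population(sc, coverage_fraction = 0.85)
  ages <- compute_age(pop$patients$birth_date, as.Date("2008-12-31"))
  realized <- table(ages, pop$patients$gender)
  for (a in 0:18) for (g in c("male", "female")) {
    expected <- round(
      (if (as.character(a) %in% rownames(realized)) realized[as.character(a), g] else 0) / 0.85)
    row <- pop$population[pop$population$year == 2008 &
                            pop$population$age_years == a &
                            pop$population$gender == g, ]
    expect_equal(row$count, expected)
  }
})

test_that("degenerate rates and missingness behave as stated", {
  drugs <- default_scenario_drugs()
  drugs$annual_rx_rate <- 0
  none <- generate_claims_dataset(small_scenario(drugs = drugs))
  expect_equal(nrow(none$dataset$prescriptions), 0)

  drugs2 <- tibble::tibble(
    atc_code = "R03AC02", annual_rx_rate = 0.5,
    dx_mixture = list(tibble::tibble(icd_code = character(0),
                                     prob = numeric(0))),
    p_missing_dx = 1
  )
  all_missing <- generate_claims_dataset(small_scenario(drugs = drugs2))
  expect_gt(nrow(all_missing$dataset$prescriptions), 0)
  expect_equal(nrow(all_missing$dataset$diagnoses), 0)
  expect_true(all(all_missing$truth$missing_dx))
})

test_that("sidecar truth and emitted events agree row-for-row", {
  sc <- simulation_scenario(n_patients = 3000, years = 2008, seed = 9,
                            p_second_dx = 0.2)
  gen <- generate_claims_dataset(sc)
  expect_equal(gen$truth$rx_id, gen$dataset$prescriptions$rx_id)
  expect_equal(gen$truth$quarter,
               (as.integer(format(gen$dataset$prescriptions$dispense_date,
                                  "%m")) + 2L) %/% 3L)
  # every non-missing truth diagnosis appears as an event in that quarter
  n_expected <- sum(!is.na(gen$truth$true_icd)) +
    sum(!is.na(gen$truth$second_icd))
  expect_equal(nrow(gen$dataset$diagnoses), n_expected)
  first <- gen$truth[!gen$truth$missing_dx, ]
  key_dx <- paste(gen$dataset$diagnoses$patient_id,
                  gen$dataset$diagnoses$icd_code,
                  gen$dataset$diagnoses$year, gen$dataset$diagnoses$quarter)
  key_truth <- paste(first$patient_id, first$true_icd, first$year,
                     first$quarter)
  expect_true(all(key_truth %in% key_dx))
})

test_that("realized prescription totals obey the law of large numbers", {
  sc <- simulation_scenario(n_patients = 20000, years = 2004:2008, seed = 3)
  gen <- generate_claims_dataset(sc)
  counts <- table(gen$dataset$prescriptions$atc_code)
  for (i in seq_len(nrow(sc$drugs))) {
    lambda <- 20000 * 5 * sc$drugs$annual_rx_rate[i]
    realized <- if (sc$drugs$atc_code[i] %in% names(counts)) {
      as.numeric(counts[sc$drugs$atc_code[i]])
    } else 0
    expect_lt(abs(realized - lambda), 3 * sqrt(lambda))
  }
})

test_that("invalid scenarios are rejected", {
  bad <- default_scenario_drugs()
  bad$p_missing_dx[1] <- 0.5  # mixture + missing no longer sums to 1
  expect_error(simulation_scenario(drugs = bad), "sum to 1")
  expect_error(simulation_scenario(n_patients = 0), "positive")
  expect_error(simulation_scenario(age_weights = rep(1, 5)), "19")
})

test_that("synthetic datasets round-trip through the disk format", {
  gen <- generate_claims_dataset(small_scenario())
  dir <- withr::local_tempdir()
  write_synthetic_dataset(gen, dir)
  back <- read_claims(file.path(dir, "patients.csv"),
                      file.path(dir, "prescriptions.csv"),
                      file.path(dir, "diagnoses.csv"))
  expect_equal(back$prescriptions, gen$dataset$prescriptions)
  pop <- read_population(file.path(dir, "population.csv"))
  expect_equal(pop, gen$population)
  expect_true(file.exists(file.path(dir, "scenario.yaml")))
})
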