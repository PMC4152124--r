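#!/usr/bin/env Rscript
# Stage 1: generate a synthetic paediatric claims dataset.
#
# Emulates the structure of a statutory-insurance ambulatory claims
# database: ~2e4 children aged 0-18, prescriptions for four respiratory
# drugs spanning the off-label rule space, quarter-resolution diagnoses
# drawn from configurable on-/off-label mixtures, and a year-end population
# table consistent with an 85% insured share. Ground truth (which mixture
# component fired per prescription) is written alongside.

suppressPackageStartupMessages(library(offlabelr))

seed <- 20260920L
out_dir <- "results/synthetic"

scenario <- simulation_scenario(
  n_patients = 20000,
  years = 2004:2008,
  p_male = 0.512,
  drugs = default_scenario_drugs(),
  p_second_dx = 0.05,    # occasional co-diagnosis: exercises multiple counting
  seed = seed
)
gen <- generate_claims_dataset(scenario, coverage_fraction = 0.85)
write_synthetic_dataset(gen, out_dir)

cat(sprintf(
  "wrote %s: %d patients, %d prescriptions, %d diagnosis rows over %d-%d\n",
  out_dir, nrow(gen$dataset$patients), nrow(gen$dataset$prescriptions),
  nrow(gen$dataset$diagnoses), min(scenario$years), max(scenario$years)
))
cat(sprintf("missing-diagnosis fraction (truth): %.3f\n",
            mean(gen$truth$missing_dx)))
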