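#!/usr/bin/env Rscript
# Stage 3: annual period prevalence rates.
#
# PPR = distinct children with >=1 prescription of the drug in the year,
# over the year-end population corrected for the 85% insured share, per
# 10,000 children. Applies the 0.1-per-10,000 inclusion threshold for the
# final year, then writes total and age-by-gender stratified tables and
# the 2004-vs-2008 PPR changes.

suppressPackageStartupMessages(library(offlabelr))

in_dir <- "results/synthetic"
out_dir <- "results/prevalence"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

config <- analysis_config()
dataset <- read_claims(file.path(in_dir, "patients.csv"),
                       file.path(in_dir, "prescriptions.csv"),
                       file.path(in_dir, "diagnoses.csv"))
dataset <- filter_study_population(dataset, config)
population <- read_population(file.path(in_dir, "population.csv"))

ppr_total <- period_prevalence(dataset, population, config, strata = "total")
included <- drug_inclusion_filter(ppr_total, config)
cat(sprintf("drugs with PPR >= %.1f per %d in %d: %s\n",
            config$inclusion_threshold_ppr, config$ppr_scale,
            config$inclusion_year, paste(included, collapse = ", ")))

ppr_strat <- period_prevalence(dataset, population, config,
                               atc_codes = included, strata = "age_gender")
readr::write_csv(ppr_total, file.path(out_dir, "ppr_total.csv"))
readr::write_csv(ppr_strat, file.path(out_dir, "ppr_age_gender.csv"))

first <- min(config$study_years); last <- max(config$study_years)
a <- ppr_total[ppr_total$year == first, ]
b <- ppr_total[ppr_total$year == last, ]
common <- intersect(a$atc_code, b$atc_code)
trends <- cbind(atc_code = common,
                ppr_change(a$ppr[match(common, a$atc_code)],
                           b$ppr[match(common, b$atc_code)]))
readr::write_csv(trends, file.path(out_dir, "ppr_trends.csv"))
cat(sprintf("PPR per %d children, %d vs %d:\n", config$ppr_scale, first, last))
print(as.data.frame(trends))
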