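#' Default pipeline configuration
#'
#' A demo-scale configuration pairing the default simulation scenario with
#' the default analysis settings. Pass the returned list (possibly edited,
#' or loaded from YAML) to [run_pipeline()].
#'
#' @param seed Master seed used for the scenario.
#' @return Nested list with elements `scenario` and `analysis`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    scenario = list(
      n_patients = 20000, years = c(2004, 2008), p_male = 0.512,
      p_second_dx = 0.05, seed = as.integer(seed)
    ),
    analysis = list(
      coverage_fraction = 0.85, ppr_scale = 10000,
      inclusion_threshold_ppr = 0.1, linkage_window = "same_quarter",
      missing_diagnosis_policy = "indeterminate",
      study_years = c(2004, 2008), max_age_years = 18,
      random_seed = as.integer(seed)
    )
  )
}

config_from_list <- function(cfg) {
  sc <- cfg$scenario %||% list()
  an <- cfg$analysis %||% list()
  years <- sc$years %||% 2004:2008
  scenario <- simulation_scenario(
    n_patients = sc$n_patients %||% 20000,
    years = sort(unique(years)),
    age_weights = sc$age_weights %||% rep(1, 19),
    p_male = sc$p_male %||% 0.512,
    drugs = sc$drugs %||% default_scenario_drugs(),
    p_second_dx = sc$p_second_dx %||% 0,
    seed = sc$seed %||% 1L
  )
  analysis <- analysis_config(
    coverage_fraction = an$coverage_fraction %||% 0.85,
    ppr_scale = an$ppr_scale %||% 10000,
    inclusion_threshold_ppr = an$inclusion_threshold_ppr %||% 0.1,
    inclusion_year = an$inclusion_year %||% NULL,
    linkage_window = an$linkage_window %||% "same_quarter",
    missing_diagnosis_policy = an$missing_diagnosis_policy %||% "indeterminate",
    study_years = an$study_years %||% scenario$years,
    max_age_years = an$max_age_years %||% 18,
    random_seed = an$random_seed %||% scenario$seed
  )
  list(scenario = scenario, analysis = analysis)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> classify -> summarise -> breakdown ->
#' prevalence -> trends on a synthetic scenario and writes every output
#' table plus a manifest into `out_dir`. Outputs are deterministic under a
#' fixed seed: reruns with an identical configuration produce byte-identical
#' analytic CSVs (the manifest's timestamp excepted).
#'
#' Outputs written: the four input tables and ground-truth sidecar,
#' `classified_prescriptions.csv`, `offlabel_summary_compound.csv`,
#' `offlabel_summary_class.csv`, `offlabel_breakdown.csv`,
#' `offlabel_trends.csv`, `ppr.csv` (drug x age x gender x year),
#' `ppr_total.csv`, `ppr_trends.csv`, and `manifest.json`.
#'
#' @param config A nested list (`scenario`, `analysis`) as from
#'   [default_pipeline_config()], or the path of a YAML file holding one.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the scenario seed.
#' @return Invisibly, a list with every in-memory result and the manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "results/pipeline", seed = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$scenario$drugs)) {
      config$scenario$drugs <- drugs_from_yaml(config$scenario$drugs)
    }
  }
  if (!is.null(seed)) {
    config$scenario$seed <- as.integer(seed)
    config$analysis$random_seed <- as.integer(seed)
  }
  parsed <- config_from_list(config)
  scenario <- parsed$scenario
  analysis <- parsed$analysis
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  message("stage 1/5: generating synthetic claims")
  gen <- generate_claims_dataset(scenario, analysis$coverage_fraction)
  write_synthetic_dataset(gen, out_dir)

  message("stage 2/5: filtering study population and classifying")
  dataset <- filter_study_population(gen$dataset, analysis)
  kb <- default_label_kb()
  classified <- classify_claims(dataset, kb, analysis)
  readr::write_csv(classified,
                   file.path(out_dir, "classified_prescriptions.csv"))

  message("stage 3/5: off-label summaries")
  final_year <- max(analysis$study_years)
  cls_final <- classified[classified$year == final_year, , drop = FALSE]
  summary_compound <- summarize_offlabel(cls_final, kb, "compound")
  summary_class <- summarize_offlabel(cls_final, kb, "class")
  breakdown <- breakdown_offlabel_indications(cls_final,
                                              default_category_map(), kb,
                                              top_k = 3, min_n = 0)
  readr::write_csv(summary_compound,
                   file.path(out_dir, "offlabel_summary_compound.csv"))
  readr::write_csv(summary_class,
                   file.path(out_dir, "offlabel_summary_class.csv"))
  readr::write_csv(breakdown, file.path(out_dir, "offlabel_breakdown.csv"))

  message("stage 4/5: prevalence and inclusion filter")
  ppr_total <- period_prevalence(dataset, gen$population, analysis,
                                 strata = "total")
  included <- drug_inclusion_filter(ppr_total, analysis)
  ppr_strat <- period_prevalence(dataset, gen$population, analysis,
                                 atc_codes = included,
                                 strata = "age_gender")
  readr::write_csv(ppr_total, file.path(out_dir, "ppr_total.csv"))
  readr::write_csv(ppr_strat, file.path(out_dir, "ppr.csv"))

  message("stage 5/5: trends")
  first_year <- min(analysis$study_years)
  off_by_year <- dplyr::count(
    classified[classified$status %in% offlabel_overall_statuses, ,
               drop = FALSE],
    .data$atc_code, .data$year, name = "n_offlabel"
  )
  wide <- tidyr::pivot_wider(off_by_year, names_from = "year",
                             values_from = "n_offlabel", values_fill = 0L)
  fy <- as.character(first_year); ly <- as.character(final_year)
  if (!fy %in% names(wide)) wide[[fy]] <- 0L
  if (!ly %in% names(wide)) wide[[ly]] <- 0L
  offlabel_trends <- dplyr::bind_cols(
    tibble(atc_code = wide$atc_code),
    offlabel_trend(wide[[fy]], wide[[ly]])
  )
  ppr_first <- ppr_total[ppr_total$year == first_year, ]
  ppr_last <- ppr_total[ppr_total$year == final_year, ]
  common <- intersect(ppr_first$atc_code, ppr_last$atc_code)
  ppr_trends <- dplyr::bind_cols(
    tibble(atc_code = common),
    ppr_change(ppr_first$ppr[match(common, ppr_first$atc_code)],
               ppr_last$ppr[match(common, ppr_last$atc_code)])
  )
  readr::write_csv(offlabel_trends, file.path(out_dir, "offlabel_trends.csv"))
  readr::write_csv(ppr_trends, file.path(out_dir, "ppr_trends.csv"))

  outputs <- list.files(out_dir, pattern = "\\.(csv|yaml)$")
  manifest <- list(
    tool = "offlabelr",
    version = as.character(utils::packageVersion("offlabelr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = scenario$seed,
    config = list(
      analysis = unclass(analysis),
      scenario = list(n_patients = scenario$n_patients,
                      years = scenario$years, p_male = scenario$p_male,
                      p_second_dx = scenario$p_second_dx,
                      drugs = scenario$drugs$atc_code)
    ),
    outputs = outputs,
    digests = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$digests) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    scenario = scenario, analysis = analysis, dataset = dataset,
    population = gen$population, truth = gen$truth, classified = classified,
    summary_compound = summary_compound, summary_class = summary_class,
    breakdown = breakdown, ppr_total = ppr_total, ppr_stratified = ppr_strat,
    offlabel_trends = offlabel_trends, ppr_trends = ppr_trends,
    manifest = manifest
  ))
}

# YAML drug blocks -> the drugs tibble of simulation_scenario()
drugs_from_yaml <- function(blocks) {
  dplyr::bind_rows(lapply(blocks, function(b) {
    tibble(
      atc_code = b$atc_code,
      annual_rx_rate = b$annual_rx_rate,
      dx_mixture = list(tibble(icd_code = names(b$dx_mixture),
                               prob = unlist(b$dx_mixture, use.names = FALSE))),
      p_missing_dx = b$p_missing_dx %||% 0
    )
  }))
}
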