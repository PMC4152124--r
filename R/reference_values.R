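#' Published reference counts (2008)
#'
#' Compound-level prescription counts for the year 2008 as printed in the
#' published Bavarian claims-database study of paediatric respiratory
#' prescribing that this pipeline reimplements: all prescriptions, the three
#' off-label type counts, and the printed off-label percentage per compound.
#' The raw claims database is not public, but every printed percentage,
#' partition sum and trend delta is an arithmetic consequence of these
#' counts, so they serve as exact desk-scale checks of the aggregation
#' arithmetic ([reference_checks()]).
#'
#' @return Tibble with one row per compound: `compound, atc_code,
#'   compound_class, n_all, n_offlabel, n_age_only, n_indication_only,
#'   n_age_and_indication, printed_pct`.
#' @export
reference_offlabel_2008 <- function() {
  tibble::tribble(
    ~compound, ~atc_code, ~compound_class, ~n_all, ~n_offlabel,
    ~n_age_only, ~n_indication_only, ~n_age_and_indication, ~printed_pct,
    "Salbutamol (inhaled)", "R03AC02", "inhaled_saba", 159655L, 67084L, 0L, 67084L, 0L, 42.0,
    "Fenoterol", "R03AC04", "inhaled_saba", 1452L, 383L, 6L, 367L, 10L, 26.4,
    "Terbutaline (inhaled)", "R03AC03", "inhaled_saba", 184L, 34L, 0L, 33L, 1L, 18.5,
    "Ipratropium/Fenoterol", "R03AK03", "inhaled_saba_combination", 3998L, 1722L, 0L, 1722L, 0L, 43.1,
    "Reproterol/Cromoglicic acid", "R03AK05", "inhaled_saba_combination", 8729L, 2538L, 0L, 2538L, 0L, 29.1,
    "Salmeterol", "R03AC12", "inhaled_laba", 522L, 86L, 9L, 75L, 2L, 16.5,
    "Formoterol", "R03AC13", "inhaled_laba", 4931L, 839L, 88L, 730L, 21L, 17.0,
    "Salmeterol/Fluticasone", "R03AK06", "inhaled_laba_ics", 27600L, 4278L, 368L, 3734L, 176L, 15.5,
    "Formoterol/Beclomethasone", "R03AK27", "inhaled_laba_ics", 2515L, 848L, 11L, 827L, 10L, 33.7,
    "Formoterol/Budesonide", "R03AK28", "inhaled_laba_ics", 13833L, 2584L, 113L, 2412L, 59L, 18.7,
    "Ipratropium", "R03BB01", "sama", 21822L, 10910L, 0L, 10910L, 0L, 50.0,
    "Tiotropium", "R03BB04", "lama", 97L, 96L, 9L, 11L, 76L, 99.0,
    "Budesonide", "R03BA02", "ics", 42067L, 3166L, 0L, 3166L, 0L, 7.5,
    "Beclomethasone", "R03BA01", "ics", 24185L, 1922L, 0L, 1922L, 0L, 7.9,
    "Fluticasone", "R03BA05", "ics", 17097L, 5360L, 1917L, 2370L, 1073L, 31.4,
    "Ciclesonide", "R03BA08", "ics", 326L, 110L, 35L, 60L, 15L, 33.7,
    "Salbutamol (oral)", "R03CC02", "oral_b2a", 19475L, 5544L, 0L, 5544L, 0L, 28.5,
    "Terbutaline (oral)", "R03CC03", "oral_b2a", 6940L, 2012L, 0L, 2012L, 0L, 29.0,
    "Tulobuterol", "R03CC11", "oral_b2a", 1201L, 330L, 32L, 292L, 6L, 27.5,
    "Clenbuterol", "R03CC13", "oral_b2a", 113L, 67L, 0L, 67L, 0L, 59.3,
    "Clenbuterol/Ambroxol", "R03CC63", "oral_b2a_combination", 91385L, 18897L, 0L, 18897L, 0L, 20.7,
    "Theophylline", "R03DA04", "other", 1184L, 451L, 7L, 419L, 25L, 38.1,
    "Montelukast", "R03DC03", "other", 33501L, 12826L, 304L, 11831L, 691L, 38.3,
    "Cromoglicic acid", "R03BC01", "other", 5087L, 3247L, 110L, 2724L, 413L, 63.8
  )
}

#' Published off-label indication counts (2008, multiple counting)
#'
#' Per-compound counts of the most frequent off-label diagnosis categories
#' among prescriptions off-label due to indication or age&indication, as
#' printed in the published breakdown (multiple counting: one count per
#' off-label diagnosis per prescription). The denominator per compound is
#' the sum of the indication-only and age&indication counts of
#' [reference_offlabel_2008()].
#'
#' @return Tibble `compound, atc_code, category_label, n_category,
#'   printed_pct`.
#' @export
reference_indication_breakdown_2008 <- function() {
  tibble::tribble(
    ~compound, ~atc_code, ~category_label, ~n_category, ~printed_pct,
    "Salbutamol (inhaled)", "R03AC02", "Acute bronchitis", 29989L, 44.7,
    "Salbutamol (inhaled)", "R03AC02", "Acute upper respiratory infections", 23827L, 35.5,
    "Salbutamol (inhaled)", "R03AC02", "Other diseases of upper respiratory tract", 13267L, 19.8,
    "Reproterol/Cromoglicic acid", "R03AK05", "Other diseases of upper respiratory tract", 999L, 39.4,
    "Reproterol/Cromoglicic acid", "R03AK05", "Acute upper respiratory infections", 402L, 15.8,
    "Reproterol/Cromoglicic acid", "R03AK05", "Bronchitis nec", 259L, 10.2,
    "Salmeterol/Fluticasone", "R03AK06", "Other diseases of upper respiratory tract", 1066L, 27.3,
    "Salmeterol/Fluticasone", "R03AK06", "Acute bronchitis", 751L, 19.2,
    "Salmeterol/Fluticasone", "R03AK06", "Acute upper respiratory infections", 679L, 17.4,
    "Formoterol/Budesonide", "R03AK28", "Other diseases of upper respiratory tract", 621L, 25.1,
    "Formoterol/Budesonide", "R03AK28", "Acute upper respiratory infections", 456L, 18.5,
    "Formoterol/Budesonide", "R03AK28", "Bronchitis nec", 428L, 17.3,
    "Ipratropium", "R03BB01", "Acute bronchitis", 5779L, 53.0,
    "Ipratropium", "R03BB01", "Acute upper respiratory infections", 4124L, 37.8,
    "Ipratropium", "R03BB01", "Bronchitis nec", 2033L, 18.6,
    "Fluticasone", "R03BA05", "Acute bronchitis", 1096L, 31.8,
    "Fluticasone", "R03BA05", "Acute upper respiratory infections", 977L, 28.4,
    "Fluticasone", "R03BA05", "Other diseases of upper respiratory tract", 847L, 24.6,
    "Salbutamol (oral)", "R03CC02", "Acute upper respiratory infections", 2431L, 43.8,
    "Salbutamol (oral)", "R03CC02", "Bronchitis nec", 2020L, 36.4,
    "Salbutamol (oral)", "R03CC02", "Other diseases of upper respiratory tract", 1001L, 18.1,
    "Terbutaline (oral)", "R03CC03", "Acute upper respiratory infections", 880L, 43.7,
    "Terbutaline (oral)", "R03CC03", "Bronchitis nec", 773L, 38.4,
    "Terbutaline (oral)", "R03CC03", "Other diseases of upper respiratory tract", 348L, 17.3,
    "Clenbuterol/Ambroxol", "R03CC63", "Acute upper respiratory infections", 9131L, 48.3,
    "Clenbuterol/Ambroxol", "R03CC63", "Other diseases of upper respiratory tract", 2767L, 14.6,
    "Clenbuterol/Ambroxol", "R03CC63", "Other respiratory diseases", 2228L, 11.8,
    "Montelukast", "R03DC03", "Acute bronchitis", 3868L, 30.9,
    "Montelukast", "R03DC03", "Acute upper respiratory infections", 3850L, 30.7,
    "Montelukast", "R03DC03", "Other diseases of upper respiratory tract", 3014L, 24.1,
    "Cromoglicic acid", "R03BC01", "Acute upper respiratory infections", 1151L, 36.7,
    "Cromoglicic acid", "R03BC01", "Acute bronchitis", 1101L, 35.1,
    "Cromoglicic acid", "R03BC01", "Other diseases of upper respiratory tract", 789L, 25.2
  )
}

#' Published off-label trend deltas (2004 vs 2008)
#'
#' The compounds highlighted in the published trend analysis: 2008 off-label
#' counts, the printed absolute change against 2004, and the printed
#' relative change. The 2004 baseline is recovered as
#' `n_2008 - absolute_change`.
#'
#' @return Tibble `compound, atc_code, n_offlabel_2008, absolute_change,
#'   printed_relative_pct`.
#' @export
reference_offlabel_trends <- function() {
  tibble::tribble(
    ~compound, ~atc_code, ~n_offlabel_2008, ~absolute_change, ~printed_relative_pct,
    "Salbutamol (inhaled)", "R03AC02", 67084L, 21841L, 48.3,
    "Salbutamol (oral)", "R03CC02", 5544L, 5422L, 4444.3,
    "Cromoglicic acid", "R03BC01", 3247L, -10195L, -75.8,
    "Clenbuterol/Ambroxol", "R03CC63", 18897L, -6196L, -24.7
  )
}

# reporting groups used in the published class totals
reference_class_groups <- function() {
  list(
    "Inhaled SABA (incl. combination)" = c("inhaled_saba",
                                           "inhaled_saba_combination"),
    "Inhaled LABA (incl. combination)" = c("inhaled_laba",
                                           "inhaled_laba_ics"),
    "Muscarinic antagonists (SAMA & LAMA)" = c("sama", "lama"),
    "Inhaled bronchodilative drugs" = inhaled_bronchodilator_classes,
    "ICS" = "ics",
    "Oral B2A (incl. combination)" = c("oral_b2a", "oral_b2a_combination"),
    "Others" = "other"
  )
}

reference_class_printed_pct <- c(
  "Inhaled SABA (incl. combination)" = 41.2,
  "Inhaled LABA (incl. combination)" = 17.5,
  "Muscarinic antagonists (SAMA & LAMA)" = 50.2,
  "Inhaled bronchodilative drugs" = 37.3,
  "ICS" = 12.6,
  "Oral B2A (incl. combination)" = 22.5,
  "Others" = 41.5
)

#' Recompute the published arithmetic from printed counts
#'
#' Recomputes, from the transcribed reference counts, every quantity the
#' published study prints as a percentage, partition sum or trend delta:
#' per-compound and per-class off-label percentages, the all-drugs partition
#' (3,009 + 139,747 + 2,578 = 145,334 of 487,899), indication-only shares,
#' the multiple-counting breakdown percentages, and the 2004-vs-2008 trend
#' deltas. Each check compares the recomputed value, rounded
#' half-away-from-zero to the printed precision, with the printed value.
#'
#' @return Tibble `check, computed, printed, pass`, where `computed` is the
#'   recomputed value at printed precision.
#' @export
reference_checks <- function() {
  ref <- reference_offlabel_2008()

  checks <- list()
  add <- function(check, computed, printed) {
    checks[[length(checks) + 1]] <<- tibble(
      check = check, computed = computed, printed = printed,
      pass = isTRUE(all.equal(computed, printed, tolerance = 1e-9))
    )
  }

  # per-compound off-label percentage and partition identity
  for (i in seq_len(nrow(ref))) {
    parts <- ref$n_age_only[i] + ref$n_indication_only[i] +
      ref$n_age_and_indication[i]
    add(sprintf("partition_%s", ref$atc_code[i]), parts, ref$n_offlabel[i])
    add(sprintf("pct_offlabel_%s", ref$atc_code[i]),
        format_pct(100 * ref$n_offlabel[i] / ref$n_all[i]),
        ref$printed_pct[i])
  }

  # class totals
  groups <- reference_class_groups()
  for (g in names(groups)) {
    rows <- ref[ref$compound_class %in% groups[[g]], ]
    add(sprintf("pct_offlabel_class_%s", g),
        format_pct(100 * sum(rows$n_offlabel) / sum(rows$n_all)),
        unname(reference_class_printed_pct[g]))
  }

  # grand totals and partition
  add("total_prescriptions", sum(ref$n_all), 487899)
  add("total_offlabel_partition",
      sum(ref$n_age_only) + sum(ref$n_indication_only) +
        sum(ref$n_age_and_indication), 145334)
  add("total_offlabel_type_age", sum(ref$n_age_only), 3009)
  add("total_offlabel_type_indication", sum(ref$n_indication_only), 139747)
  add("total_offlabel_type_age_and_indication",
      sum(ref$n_age_and_indication), 2578)
  add("pct_offlabel_all_drugs",
      format_pct(100 * sum(ref$n_offlabel) / sum(ref$n_all)), 29.8)

  # indication-only shares of off-label prescriptions
  bronch <- ref[ref$compound_class %in% inhaled_bronchodilator_classes, ]
  add("indication_only_share_inhaled_bronchodilators",
      format_pct(100 * sum(bronch$n_indication_only) /
                   sum(bronch$n_offlabel)), 99.0)
  oral <- ref[ref$compound_class %in% c("oral_b2a", "oral_b2a_combination"), ]
  add("indication_only_share_oral_b2a",
      format_pct(100 * sum(oral$n_indication_only) / sum(oral$n_offlabel)),
      99.9)

  # multiple-counting breakdown percentages (denominator: indication +
  # age&indication counts)
  brk <- reference_indication_breakdown_2008()
  denom <- (ref$n_indication_only + ref$n_age_and_indication)[
    match(brk$atc_code, ref$atc_code)]
  for (i in seq_len(nrow(brk))) {
    add(sprintf("breakdown_pct_%s_%s", brk$atc_code[i],
                gsub("[^A-Za-z]+", "_", brk$category_label[i])),
        format_pct(100 * brk$n_category[i] / denom[i]),
        brk$printed_pct[i])
  }

  # trend deltas: baseline recovered from 2008 count minus absolute change
  tr <- reference_offlabel_trends()
  base <- tr$n_offlabel_2008 - tr$absolute_change
  rel <- offlabel_trend(base, tr$n_offlabel_2008)$relative_change_pct
  for (i in seq_len(nrow(tr))) {
    add(sprintf("trend_relative_pct_%s", tr$atc_code[i]),
        format_pct(rel[i]), tr$printed_relative_pct[i])
  }

  dplyr::bind_rows(checks)
}
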