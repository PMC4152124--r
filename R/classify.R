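#' Off-label status values
#'
#' Every prescription receives exactly one of five statuses: `ON_LABEL`
#' (age and at least one linked diagnosis approved), `OFF_AGE` (patient
#' younger than the approved minimum age, diagnosis approved),
#' `OFF_INDICATION` (age approved, no linked diagnosis approved),
#' `OFF_AGE_AND_INDICATION` (both rules fail), or `INDETERMINATE` (no
#' linked diagnosis under the default missing-diagnosis policy).
#'
#' @export
offlabel_statuses <- c("ON_LABEL", "OFF_AGE", "OFF_INDICATION",
                       "OFF_AGE_AND_INDICATION", "INDETERMINATE")

offlabel_overall_statuses <- c("OFF_AGE", "OFF_INDICATION",
                               "OFF_AGE_AND_INDICATION")

#' Classify one prescription against an effective label
#'
#' The age rule passes when age at dispense is at least the label's minimum
#' age; the indication rule passes when any linked diagnosis code matches
#' the label's indication prefixes (a prescription is off-label by
#' indication only if every linked diagnosis is non-approved, the widest
#' reading of the label). With no linked diagnosis the
#' `missing_diagnosis_policy` governs: `"indeterminate"` (default) returns
#' `INDETERMINATE`; `"on_label"` treats the indication rule as passed;
#' `"off_label_indication"` as failed.
#'
#' @param age_at_dispense Age in completed years at the dispense date.
#' @param linked_codes Character vector of ICD-10 codes documented in the
#'   linkage window (may be empty).
#' @param label One-row effective label from [resolve_effective_label()].
#' @param policy Missing-diagnosis policy.
#' @return A single status string (see [offlabel_statuses]).
#' @export
#' @examples
#' kb <- default_label_kb()
#' tio <- resolve_effective_label(kb[kb$atc_code == "R03BB04", ])
#' classify_prescription(10, "J45.0", tio)  # OFF_AGE_AND_INDICATION
classify_prescription <- function(age_at_dispense, linked_codes, label,
                                  policy = c("indeterminate", "on_label",
                                             "off_label_indication")) {
  policy <- match.arg(policy)
  age_ok <- age_at_dispense >= label$min_age_years
  linked_codes <- linked_codes[!is.na(linked_codes)]
  if (length(linked_codes) == 0) {
    if (policy == "indeterminate") return("INDETERMINATE")
    ind_ok <- policy == "on_label"
  } else {
    ind_ok <- any(match_icd(linked_codes, label$indication_codes[[1]]))
  }
  if (age_ok && ind_ok) "ON_LABEL"
  else if (!age_ok && ind_ok) "OFF_AGE"
  else if (age_ok && !ind_ok) "OFF_INDICATION"
  else "OFF_AGE_AND_INDICATION"
}

#' Classify every prescription in a claims dataset
#'
#' Links diagnoses to prescriptions (per the configured window), resolves
#' effective labels from the KB, and applies the age and indication rules to
#' every prescription at once. Prescriptions whose ATC code has no KB record
#' raise an error.
#'
#' @param dataset A `claims_dataset` (typically already passed through
#'   [filter_study_population()]).
#' @param kb Label KB tibble (default: packaged KB).
#' @param config An [analysis_config()].
#' @return Tibble with one row per prescription: `rx_id`, `patient_id`,
#'   `atc_code`, `year`, `age_at_dispense`, `n_linked_dx`, `status`, and
#'   `offlabel_codes` (semicolon-separated linked codes not matching the
#'   label; the basis of the indication breakdown).
#' @export
classify_claims <- function(dataset, kb = default_label_kb(),
                            config = analysis_config()) {
  stopifnot(inherits(dataset, "claims_dataset"))
  labels <- resolve_labels(kb)
  rx <- dataset$prescriptions
  unknown <- setdiff(unique(rx$atc_code), labels$atc_code)
  if (length(unknown) > 0) {
    stop_offlabelr(
      sprintf("prescriptions carry ATC code(s) absent from the label KB: %s",
              paste(unknown, collapse = ", ")),
      class = "offlabelr_validation_error"
    )
  }
  if (nrow(rx) == 0) {
    return(tibble(rx_id = character(0), patient_id = character(0),
                  atc_code = character(0), year = integer(0),
                  age_at_dispense = integer(0), n_linked_dx = integer(0),
                  status = character(0), offlabel_codes = character(0)))
  }
  rx <- dplyr::left_join(
    rx, dplyr::select(dataset$patients, "patient_id", "birth_date"),
    by = "patient_id"
  )
  rx$year <- as.integer(format(rx$dispense_date, "%Y"))
  rx$age_at_dispense <- compute_age(rx$birth_date, rx$dispense_date)

  linked <- link_diagnoses(dataset$prescriptions, dataset$diagnoses,
                           config$linkage_window)
  if (nrow(linked) > 0) {
    linked <- dplyr::left_join(
      linked,
      dplyr::select(rx, "rx_id", "atc_code"),
      by = "rx_id"
    )
    # per linked code: does it match the label of the prescription's drug?
    linked$matched <- FALSE
    for (i in seq_len(nrow(labels))) {
      sel <- linked$atc_code == labels$atc_code[i]
      if (any(sel)) {
        linked$matched[sel] <- match_icd(linked$icd_code[sel],
                                         labels$indication_codes[[i]])
      }
    }
    per_rx <- dplyr::summarise(
      dplyr::group_by(linked, .data$rx_id),
      n_linked_dx = dplyr::n(),
      ind_ok = any(.data$matched),
      offlabel_codes = paste(sort(.data$icd_code[!.data$matched]),
                             collapse = ";"),
      .groups = "drop"
    )
  } else {
    per_rx <- tibble(rx_id = character(0), n_linked_dx = integer(0),
                     ind_ok = logical(0), offlabel_codes = character(0))
  }

  out <- dplyr::left_join(rx, per_rx, by = "rx_id")
  out$n_linked_dx[is.na(out$n_linked_dx)] <- 0L
  out$offlabel_codes[is.na(out$offlabel_codes)] <- ""
  no_dx <- out$n_linked_dx == 0L
  out$ind_ok[no_dx] <- switch(
    config$missing_diagnosis_policy,
    indeterminate = NA,
    on_label = TRUE,
    off_label_indication = FALSE
  )
  min_age <- labels$min_age_years[match(out$atc_code, labels$atc_code)]
  age_ok <- out$age_at_dispense >= min_age
  status <- dplyr::case_when(
    is.na(out$ind_ok) ~ "INDETERMINATE",
    age_ok & out$ind_ok ~ "ON_LABEL",
    !age_ok & out$ind_ok ~ "OFF_AGE",
    age_ok & !out$ind_ok ~ "OFF_INDICATION",
    TRUE ~ "OFF_AGE_AND_INDICATION"
  )
  tibble(
    rx_id = out$rx_id,
    patient_id = out$patient_id,
    atc_code = out$atc_code,
    year = out$year,
    age_at_dispense = out$age_at_dispense,
    n_linked_dx = out$n_linked_dx,
    status = status,
    offlabel_codes = out$offlabel_codes
  )
}

#' Summarise off-label classification
#'
#' Tabulates classified prescriptions per compound, per compound class, or
#' in total: all prescriptions, off-label overall (the sum of the three
#' off-label types), percentage off-label, the three type counts, and the
#' indeterminate count. A grand-total row (`"All drugs"`) is always
#' appended. Percentages are kept at full precision; apply [format_pct()]
#' for table display.
#'
#' @param classified Output of [classify_claims()].
#' @param kb Label KB (used to map ATC codes to names and classes).
#' @param grouping `"compound"`, `"class"`, or `"total"`.
#' @return Tibble of summary rows with columns `group`, `n_all`,
#'   `n_offlabel_overall`, `pct_offlabel`, `n_age_only`,
#'   `n_indication_only`, `n_age_and_indication`, `n_indeterminate`.
#' @export
summarize_offlabel <- function(classified, kb = default_label_kb(),
                               grouping = c("compound", "class", "total")) {
  grouping <- match.arg(grouping)
  labels <- resolve_labels(kb)
  group <- switch(
    grouping,
    compound = labels$compound_name[match(classified$atc_code,
                                          labels$atc_code)],
    class = labels$compound_class[match(classified$atc_code,
                                        labels$atc_code)],
    total = rep("All drugs", nrow(classified))
  )
  tab <- tally_offlabel(tibble(group = group, status = classified$status))
  if (grouping != "total") {
    total <- tally_offlabel(tibble(group = "All drugs",
                                   status = classified$status))
    tab <- dplyr::bind_rows(tab, total)
  }
  tab
}

tally_offlabel <- function(df) {
  if (nrow(df) == 0) {
    return(tibble(group = "All drugs", n_all = 0L, n_offlabel_overall = 0L,
                  pct_offlabel = NA_real_, n_age_only = 0L,
                  n_indication_only = 0L, n_age_and_indication = 0L,
                  n_indeterminate = 0L))
  }
  dplyr::summarise(
    dplyr::group_by(df, .data$group),
    n_all = dplyr::n(),
    n_age_only = sum(.data$status == "OFF_AGE"),
    n_indication_only = sum(.data$status == "OFF_INDICATION"),
    n_age_and_indication = sum(.data$status == "OFF_AGE_AND_INDICATION"),
    n_indeterminate = sum(.data$status == "INDETERMINATE"),
    .groups = "drop"
  ) |>
    dplyr::mutate(
      n_offlabel_overall = .data$n_age_only + .data$n_indication_only +
        .data$n_age_and_indication,
      pct_offlabel = 100 * .data$n_offlabel_overall / .data$n_all
    ) |>
    dplyr::select("group", "n_all", "n_offlabel_overall", "pct_offlabel",
                  "n_age_only", "n_indication_only", "n_age_and_indication",
                  "n_indeterminate")
}

#' Off-label indication breakdown with multiple counting
#'
#' For prescriptions off-label by indication (`OFF_INDICATION` or
#' `OFF_AGE_AND_INDICATION`), tabulates the non-approved diagnosis codes by
#' reporting category. Every off-label code on every such prescription
#' increments its category (multiple counting), so category percentages may
#' sum above 100. The percentage denominator per compound is the number of
#' prescriptions off-label due to indication or age&indication;
#' prescriptions with no linked diagnosis never enter (they are
#' indeterminate under the default policy, and carry no codes otherwise).
#'
#' @param classified Output of [classify_claims()].
#' @param category_map A `diagnosis_category_map`.
#' @param kb Label KB (for compound names).
#' @param top_k Keep the `top_k` most frequent categories per compound
#'   (default 3).
#' @param min_n Only report compounds with at least `min_n` prescriptions
#'   overall (default 5000; set 0 to disable).
#' @return Tibble `compound, atc_code, category_label, n_category,
#'   pct_of_offlabel, n_offlabel_denominator`, sorted by descending count
#'   within compound.
#' @export
breakdown_offlabel_indications <- function(classified,
                                           category_map = default_category_map(),
                                           kb = default_label_kb(),
                                           top_k = 3, min_n = 5000) {
  labels <- resolve_labels(kb)
  n_all <- table(classified$atc_code)
  keep_atc <- names(n_all)[n_all >= min_n]
  # prescriptions with no linked diagnosis are excluded from the breakdown
  # entirely (they carry no indication to count)
  cls <- classified[classified$atc_code %in% keep_atc &
                      classified$n_linked_dx > 0 &
                      classified$status %in% c("OFF_INDICATION",
                                               "OFF_AGE_AND_INDICATION"), ,
                    drop = FALSE]
  if (nrow(cls) == 0) {
    return(tibble(compound = character(0), atc_code = character(0),
                  category_label = character(0), n_category = integer(0),
                  pct_of_offlabel = numeric(0),
                  n_offlabel_denominator = integer(0)))
  }
  denom <- dplyr::count(cls, .data$atc_code, name = "n_offlabel_denominator")
  codes <- tibble(
    atc_code = rep(cls$atc_code,
                   lengths(strsplit(cls$offlabel_codes, ";", fixed = TRUE))),
    icd_code = unlist(strsplit(cls$offlabel_codes, ";", fixed = TRUE))
  )
  codes <- codes[nzchar(codes$icd_code), , drop = FALSE]
  codes$category_label <- categorize_diagnosis(codes$icd_code, category_map)
  counts <- dplyr::count(codes, .data$atc_code, .data$category_label,
                         name = "n_category")
  counts <- dplyr::left_join(counts, denom, by = "atc_code")
  counts$pct_of_offlabel <- 100 * counts$n_category /
    counts$n_offlabel_denominator
  counts$compound <- labels$compound_name[match(counts$atc_code,
                                                labels$atc_code)]
  counts <- dplyr::arrange(counts, .data$compound,
                           dplyr::desc(.data$n_category),
                           .data$category_label)
  counts <- dplyr::slice_head(dplyr::group_by(counts, .data$atc_code),
                              n = top_k)
  dplyr::select(dplyr::ungroup(counts), "compound", "atc_code",
                "category_label", "n_category", "pct_of_offlabel",
                "n_offlabel_denominator")
}

#' Off-label trend between two years
#'
#' Absolute and relative change in off-label prescription counts between a
#' baseline and a comparison year. The relative change is undefined (NA,
#' flagged `not_applicable`) when the baseline count is zero.
#'
#' @param n_year_a Baseline count (vectorised).
#' @param n_year_b Comparison count.
#' @return Tibble `n_year_a, n_year_b, absolute_change, relative_change_pct,
#'   not_applicable`.
#' @export
#' @examples
#' offlabel_trend(45243, 67084)  # +21841, +48.3%
offlabel_trend <- function(n_year_a, n_year_b) {
  if (any(n_year_a < 0) || any(n_year_b < 0)) {
    stop_offlabelr("counts must be non-negative")
  }
  abs_change <- n_year_b - n_year_a
  rel <- ifelse(n_year_a == 0, NA_real_, 100 * abs_change / n_year_a)
  tibble(
    n_year_a = n_year_a, n_year_b = n_year_b,
    absolute_change = abs_change,
    relative_change_pct = rel,
    not_applicable = n_year_a == 0
  )
}
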