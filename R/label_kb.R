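#' Drug-label knowledge base
#'
#' The label knowledge base (KB) encodes, per ATC code and SPC snapshot year,
#' the approved minimum age and the approved indications expressed as ICD-10
#' code prefixes. The shipped default covers the 24 respiratory compounds
#' (ATC group R03) analysed by the pipeline: inhaled short- and long-acting
#' beta-2-agonists and their fixed combinations, muscarinic antagonists,
#' inhaled corticosteroids, oral beta-2-agonists, theophylline, montelukast
#' and cromoglicic acid. A minimum age of 0 encodes "no age restriction".
#'
#' Indications on a drug label are prose ("asthma", "COPD"); the KB maps them
#' to ICD-10 block prefixes (asthma -> J45, J46; COPD -> J44; emphysema ->
#' J43; chronic bronchitis -> J41, J42; acute bronchitis -> J20). The mapping
#' is an editable data asset, not code: pass a different file to
#' [load_label_kb()] to change it.
#'
#' @name label_kb
NULL

compound_classes <- c(
  "inhaled_saba", "inhaled_saba_combination", "inhaled_laba",
  "inhaled_laba_ics", "sama", "lama", "ics", "oral_b2a",
  "oral_b2a_combination", "other"
)

# classes forming the "inhaled bronchodilative drugs" reporting group
inhaled_bronchodilator_classes <- c(
  "inhaled_saba", "inhaled_saba_combination", "inhaled_laba",
  "inhaled_laba_ics", "sama", "lama"
)

atc_pattern <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
icd_lexical_pattern <- "^[A-Z][0-9]{2}"

#' Load a drug-label knowledge base
#'
#' Reads a CSV with columns `atc_code`, `compound_name`, `compound_class`,
#' `min_age_years`, `indication_prefixes` (semicolon-separated ICD-10
#' prefixes), `source_year` and optional `device_or_product_note`, validates
#' every row, and returns one label record per (ATC code, SPC source year).
#'
#' @param path Path to the KB file. Defaults to the packaged KB encoding the
#'   approved labels of the 24 analysed respiratory compounds for the 2004
#'   and 2008 SPC snapshots.
#' @return A tibble of label records with `indication_codes` as a list-column
#'   of character vectors.
#' @seealso [resolve_effective_label()], [default_label_kb()]
#' @export
load_label_kb <- function(path = system.file("extdata", "label_kb.csv",
                                             package = "offlabelr")) {
  if (!file.exists(path)) {
    stop_offlabelr(sprintf("label KB file not found: %s", path))
  }
  kb <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          atc_code = readr::col_character(),
                          compound_name = readr::col_character(),
                          compound_class = readr::col_character(),
                          min_age_years = readr::col_integer(),
                          indication_prefixes = readr::col_character(),
                          source_year = readr::col_integer(),
                          .default = readr::col_character()
                        ))
  if (nrow(kb) == 0) {
    stop_offlabelr("label KB is empty: no records",
                   class = "offlabelr_validation_error")
  }
  assert_columns(kb, c("atc_code", "compound_name", "compound_class",
                       "min_age_years", "indication_prefixes", "source_year"),
                 "label KB")
  kb$indication_prefixes[is.na(kb$indication_prefixes)] <- ""
  kb$indication_codes <- lapply(strsplit(kb$indication_prefixes, ";",
                                         fixed = TRUE),
                                function(p) normalize_icd(p[nzchar(p)]))
  validate_label_records(kb)
  kb
}

#' @rdname load_label_kb
#' @export
default_label_kb <- function() load_label_kb()

validate_label_records <- function(kb) {
  bad_atc <- which(!grepl(atc_pattern, kb$atc_code))
  if (length(bad_atc) > 0) {
    stop_offlabelr(
      sprintf("malformed ATC code in KB row(s) %s: %s",
              paste(bad_atc, collapse = ", "),
              paste(unique(kb$atc_code[bad_atc]), collapse = ", ")),
      class = "offlabelr_validation_error"
    )
  }
  bad_class <- which(!kb$compound_class %in% compound_classes)
  if (length(bad_class) > 0) {
    stop_offlabelr(
      sprintf("unknown compound class in KB row(s) %s: %s",
              paste(bad_class, collapse = ", "),
              paste(unique(kb$compound_class[bad_class]), collapse = ", ")),
      class = "offlabelr_validation_error"
    )
  }
  bad_age <- which(is.na(kb$min_age_years) | kb$min_age_years < 0 |
                     kb$min_age_years > 18)
  if (length(bad_age) > 0) {
    stop_offlabelr(
      sprintf("min_age_years outside [0, 18] in KB row(s) %s",
              paste(bad_age, collapse = ", ")),
      class = "offlabelr_validation_error"
    )
  }
  empty_ind <- which(vapply(kb$indication_codes, length, 1L) == 0)
  if (length(empty_ind) > 0) {
    stop_offlabelr(
      sprintf("empty indication set in KB row(s) %s",
              paste(empty_ind, collapse = ", ")),
      class = "offlabelr_validation_error"
    )
  }
  invisible(kb)
}

#' Resolve the effective label for one ATC code
#'
#' When several label records exist for one compound (different SPC snapshot
#' years or devices), the effective label takes the lowest age restriction
#' and the widest (union) indication set across records, so a prescription is
#' counted as off-label only when it falls outside every version of the label.
#'
#' @param records Label records (as from [load_label_kb()]) sharing one
#'   `atc_code`.
#' @return One-row tibble with `atc_code`, `min_age_years` (minimum across
#'   records), `indication_codes` (union, as a list-column), and
#'   `n_source_records`.
#' @export
#' @examples
#' kb <- default_label_kb()
#' resolve_effective_label(kb[kb$atc_code == "R03BB04", ])
resolve_effective_label <- function(records) {
  if (nrow(records) == 0) {
    stop_offlabelr("cannot resolve an effective label from zero records")
  }
  atc <- unique(records$atc_code)
  if (length(atc) != 1) {
    stop_offlabelr(
      sprintf("records mix ATC codes: %s", paste(atc, collapse = ", "))
    )
  }
  tibble(
    atc_code = atc,
    min_age_years = min(records$min_age_years),
    indication_codes = list(sort(unique(unlist(records$indication_codes)))),
    n_source_records = nrow(records)
  )
}

#' Resolve effective labels for every compound in a KB
#'
#' @param kb A label KB tibble.
#' @return Tibble with one effective label per ATC code, carrying the
#'   compound name and class of the first source record.
#' @export
resolve_labels <- function(kb) {
  meta <- dplyr::distinct(kb, .data$atc_code, .keep_all = TRUE)
  eff <- dplyr::bind_rows(lapply(
    split(kb, kb$atc_code), resolve_effective_label
  ))
  dplyr::left_join(
    eff,
    dplyr::select(meta, "atc_code", "compound_name", "compound_class"),
    by = "atc_code"
  )
}

#' Normalize an ICD-10 code for matching
#'
#' Uppercases and strips dots, so `"j45.9"` and `"J459"` compare equal.
#'
#' @param code Character vector of ICD-10 codes or prefixes.
#' @return Normalized character vector.
#' @export
normalize_icd <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

#' Match an ICD-10 code against a set of prefixes
#'
#' A code matches if its normalized form (uppercase, dot stripped) begins
#' with any normalized prefix. Codes failing the ICD-10 lexical pattern
#' (letter + two digits) never match and are reported once via a warning.
#'
#' @param code Character vector of ICD-10 codes.
#' @param prefixes Character vector of ICD-10 prefixes.
#' @return Logical vector, one element per code.
#' @export
#' @examples
#' match_icd(c("J45.9", "J20.5", "j459"), c("J45", "J46"))
match_icd <- function(code, prefixes) {
  norm <- normalize_icd(code)
  valid <- grepl(icd_lexical_pattern, norm)
  if (any(!valid)) {
    warn(sprintf("ignoring %d code(s) failing the ICD-10 pattern: %s",
                 sum(!valid),
                 paste(utils::head(unique(code[!valid]), 5), collapse = ", ")))
  }
  prefixes <- normalize_icd(prefixes)
  hit <- rep(FALSE, length(norm))
  for (p in prefixes) {
    hit <- hit | startsWith(norm, p)
  }
  hit & valid
}

#' Load a diagnosis category map
#'
#' The category map turns ICD-10 codes into the reporting vocabulary used in
#' the off-label indication breakdown ("Acute upper respiratory infections",
#' "Acute bronchitis", "Bronchitis nec", ...). Rows are ordered and matching
#' is first-match-wins, so a final catch-all prefix (`J` for "Other
#' respiratory diseases") is allowed; codes matching no row fall through to
#' `fallback_label`.
#'
#' @param path CSV with ordered columns `category_label`, `icd_prefixes`
#'   (semicolon-separated). Defaults to the packaged map following ICD-10
#'   block headings (J00-J06, J20, J21-J22, J30-J39, J40, J43-J44, remaining
#'   J-chapter).
#' @param fallback_label Label for codes matching no row (default
#'   `"Non-respiratory"`).
#' @return A list with `categories` (tibble with list-column `prefixes`) and
#'   `fallback_label`, class `"diagnosis_category_map"`.
#' @export
load_category_map <- function(path = system.file("extdata",
                                                 "diagnosis_categories.csv",
                                                 package = "offlabelr"),
                              fallback_label = "Non-respiratory") {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  assert_columns(raw, c("category_label", "icd_prefixes"), "category map")
  raw$prefixes <- lapply(strsplit(raw$icd_prefixes, ";", fixed = TRUE),
                         function(p) normalize_icd(p[nzchar(p)]))
  map <- structure(
    list(categories = raw, fallback_label = fallback_label),
    class = "diagnosis_category_map"
  )
  validate_category_map(map)
  map
}

#' @rdname load_category_map
#' @export
default_category_map <- function() load_category_map()

# every row must be reachable: no prefix of a later row may extend a prefix
# of an earlier row (which would already have captured the code)
validate_category_map <- function(map) {
  cats <- map$categories
  seen <- character(0)
  for (i in seq_len(nrow(cats))) {
    for (p in cats$prefixes[[i]]) {
      shadowed <- any(vapply(seen, function(s) startsWith(p, s), TRUE))
      if (shadowed) {
        stop_offlabelr(
          sprintf("category '%s' prefix '%s' is unreachable: shadowed by an earlier row",
                  cats$category_label[i], p),
          class = "offlabelr_validation_error"
        )
      }
    }
    seen <- c(seen, cats$prefixes[[i]])
  }
  invisible(map)
}

#' Categorize ICD-10 diagnosis codes
#'
#' Assigns each code to the first category of the map whose prefix set
#' matches; codes matching no row get the map's fallback label. Assignment is
#' invariant to dot/case formatting of the code.
#'
#' @param code Character vector of ICD-10 codes.
#' @param map A `diagnosis_category_map` (default: packaged map).
#' @return Character vector of category labels, one per code.
#' @export
#' @examples
#' categorize_diagnosis(c("J20.9", "J06.9", "K52.9"))
categorize_diagnosis <- function(code, map = default_category_map()) {
  stopifnot(inherits(map, "diagnosis_category_map"))
  out <- rep(map$fallback_label, length(code))
  unassigned <- rep(TRUE, length(code))
  cats <- map$categories
  for (i in seq_len(nrow(cats))) {
    hit <- unassigned & suppressWarnings(match_icd(code, cats$prefixes[[i]]))
    out[hit] <- cats$category_label[i]
    unassigned[hit] <- FALSE
  }
  out
}
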