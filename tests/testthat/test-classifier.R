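kb <- test_kb()
labels <- resolve_labels(kb)
label_of <- function(atc) labels[labels$atc_code == atc, ]

test_that("the age and indication rules partition prescriptions", {
  # adult-only COPD drug in a 10-year-old asthmatic: both rules fail
  expect_equal(classify_prescription(10, "J45.0", label_of("R03BB04")),
               "OFF_AGE_AND_INDICATION")
  # broad bronchodilator, approved diagnosis, no age floor
  expect_equal(classify_prescription(3, "J45.9", label_of("R03AC02")),
               "ON_LABEL")
  # acute bronchitis is not on this label: off-label by indication
  expect_equal(classify_prescription(3, "J20.9", label_of("R03AC02")),
               "OFF_INDICATION")
  # age floor of 4 with an approved diagnosis: off-label by age only
  expect_equal(classify_prescription(2, "J45.0", label_of("R03AC04")),
               "OFF_AGE")
  # any-match rule: one approved code among off-label codes is on-label
  expect_equal(classify_prescription(10, c("J20.9", "J45.9"),
                                     label_of("R03AC02")), "ON_LABEL")
})

test_that("missing diagnoses follow the configured policy", {
  lab <- label_of("R03AC04")
  expect_equal(classify_prescription(10, character(0), lab), "INDETERMINATE")
  expect_equal(classify_prescription(2, character(0), lab), "INDETERMINATE")
  expect_equal(classify_prescription(10, character(0), lab, "on_label"),
               "ON_LABEL")
  expect_equal(classify_prescription(2, character(0), lab, "on_label"),
               "OFF_AGE")
  expect_equal(classify_prescription(10, character(0), lab,
                                     "off_label_indication"),
               "OFF_INDICATION")
  expect_equal(classify_prescription(2, character(0), lab,
                                     "off_label_indication"),
               "OFF_AGE_AND_INDICATION")
})

test_that("dataset-level classification matches the single-rx rule", {
  patients <- make_patients(4, birth_years = c(2006, 2000, 1995, 2004),
                            gender = c("male", "female", "male", "female"))
  rx <- make_rx(patients$patient_id,
                c("R03AC04", "R03AC02", "R03BB04", "R03AC02"),
                c("2008-05-10", "2008-02-01", "2008-08-15", "2008-11-02"))
  dx <- make_dx(patients$patient_id[c(1, 2, 3)],
                c("J45.9", "J20.9", "J45.0"),
                2008, c(2, 1, 3))
  ds <- claims_dataset(patients, rx, dx)
  out <- classify_claims(ds, kb)
  expect_equal(out$status,
               c("OFF_AGE",                 # age 1 (born 2006-06-15), J45
                 "OFF_INDICATION",          # age 8, J20 not approved
                 "OFF_AGE_AND_INDICATION",  # age 13 < 18, J45 not approved
                 "INDETERMINATE"))          # no diagnosis in Q4
  expect_equal(out$offlabel_codes, c("", "J20.9", "J45.0", ""))
  expect_equal(out$n_linked_dx, c(1L, 1L, 1L, 0L))
})

test_that("summaries satisfy the partition identity and the stated arithmetic", {
  statuses <- c(rep("OFF_AGE", 2), rep("OFF_INDICATION", 3),
                "OFF_AGE_AND_INDICATION", rep("ON_LABEL", 4))
  classified <- tibble::tibble(
    rx_id = sprintf("R%02d", 1:10), patient_id = "P001",
    atc_code = "R03AC02", year = 2008L, age_at_dispense = 5L,
    n_linked_dx = 1L, status = statuses, offlabel_codes = ""
  )
  s <- summarize_offlabel(classified, kb, "total")
  expect_equal(s$n_all, 10)
  expect_equal(s$n_offlabel_overall, 6)
  expect_equal(s$pct_offlabel, 60.0)
  expect_equal(s$n_offlabel_overall,
               s$n_age_only + s$n_indication_only + s$n_age_and_indication)

  empty <- summarize_offlabel(classified[0, ], kb, "total")
  expect_equal(empty$n_all, 0)
  expect_equal(empty$n_offlabel_overall, 0)
})

test_that("partition identity holds on every summary row of random data", {
  set.seed(21)
  for (i in 1:10) {
    ds <- random_claims(300)
    out <- classify_claims(ds, kb)
    for (grouping in c("compound", "class", "total")) {
      s <- summarize_offlabel(out, kb, grouping)
      expect_equal(s$n_offlabel_overall,
                   s$n_age_only + s$n_indication_only +
                     s$n_age_and_indication)
      expect_equal(s$n_all,
                   s$n_offlabel_overall + s$n_indeterminate +
                     (s$n_all - s$n_offlabel_overall - s$n_indeterminate))
      expect_true(all(s$n_all >= s$n_offlabel_overall + s$n_indeterminate))
    }
    # totals row equals the sum of the compound rows
    s <- summarize_offlabel(out, kb, "compound")
    tot <- s[s$group == "All drugs", ]
    cmp <- s[s$group != "All drugs", ]
    expect_equal(tot$n_all, sum(cmp$n_all))
    expect_equal(tot$n_offlabel_overall, sum(cmp$n_offlabel_overall))
  }
})

test_that("relaxing the label is monotone in the off-label direction", {
  set.seed(31)
  kb0 <- test_kb()
  for (i in 1:5) {
    ds <- random_claims(300)
    base <- classify_claims(ds, kb0)
    # dropping every age floor turns OFF_AGE into ON_LABEL and
    # OFF_AGE_AND_INDICATION into OFF_INDICATION, nothing else changes
    kb_noage <- kb0
    kb_noage$min_age_years <- 0L
    relaxed <- classify_claims(ds, kb_noage)
    map <- c(ON_LABEL = "ON_LABEL", OFF_AGE = "ON_LABEL",
             OFF_INDICATION = "OFF_INDICATION",
             OFF_AGE_AND_INDICATION = "OFF_INDICATION",
             INDETERMINATE = "INDETERMINATE")
    expect_equal(relaxed$status, unname(map[base$status]))
    # widening every indication set never increases off-label counts
    kb_wide <- kb0
    kb_wide$indication_codes <- lapply(kb_wide$indication_codes,
                                       function(x) unique(c(x, "J20")))
    wider <- classify_claims(ds, kb_wide)
    n_off <- function(cl) sum(cl$status %in% c("OFF_AGE", "OFF_INDICATION",
                                               "OFF_AGE_AND_INDICATION"))
    expect_lte(n_off(wider), n_off(base))
  }
})

test_that("indication breakdown multiple-counts off-label codes", {
  classified <- tibble::tibble(
    rx_id = "R01", patient_id = "P001", atc_code = "R03AC02", year = 2008L,
    age_at_dispense = 5L, n_linked_dx = 2L, status = "OFF_INDICATION",
    offlabel_codes = "J20.9;J06.9"
  )
  b <- breakdown_offlabel_indications(classified, kb = kb, min_n = 0)
  expect_setequal(b$category_label,
                  c("Acute bronchitis", "Acute upper respiratory infections"))
  expect_equal(b$n_category, c(1L, 1L))
  expect_equal(b$pct_of_offlabel, c(100, 100))
  expect_equal(unique(b$n_offlabel_denominator), 1L)

  # no off-label prescriptions for a compound -> no rows
  onlab <- classified
  onlab$status <- "ON_LABEL"
  expect_equal(nrow(breakdown_offlabel_indications(onlab, kb = kb,
                                                   min_n = 0)), 0)
})

test_that("breakdown respects top_k and the minimum-prescription filter", {
  set.seed(41)
  ds <- random_claims(600)
  out <- classify_claims(ds, kb)
  b_all <- breakdown_offlabel_indications(out, kb = kb, top_k = 2, min_n = 0)
  expect_true(all(table(b_all$atc_code) <= 2))
  # a very high min_n excludes every compound
  b_none <- breakdown_offlabel_indications(out, kb = kb, min_n = 10000)
  expect_equal(nrow(b_none), 0)
})

test_that("off-label trend deltas reproduce the published idiom", {
  tr <- offlabel_trend(45243, 67084)
  expect_equal(tr$absolute_change, 21841)
  expect_equal(format_pct(tr$relative_change_pct), 48.3)
  tr2 <- offlabel_trend(122, 5544)
  expect_equal(tr2$absolute_change, 5422)
  expect_equal(format_pct(tr2$relative_change_pct), 4444.3)
  tr3 <- offlabel_trend(500, 500)
  expect_equal(tr3$absolute_change, 0)
  expect_equal(tr3$relative_change_pct, 0)
  tr0 <- offlabel_trend(0, 5)
  expect_true(tr0$not_applicable)
  expect_true(is.na(tr0$relative_change_pct))
})
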