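test_that("shipped KB covers the analysed compounds with valid records", {
  kb <- default_label_kb()
  expect_equal(length(unique(kb$atc_code)), 24)
  expect_setequal(unique(kb$source_year), c(2004L, 2008L))
  # adult-only anticholinergic: approved from 18 years, COPD only
  tio <- kb[kb$atc_code == "R03BB04", ]
  expect_true(all(tio$min_age_years == 18))
  expect_equal(tio$indication_codes[[1]], "J44")
  # inhaled salbutamol: no age restriction
  sal <- kb[kb$atc_code == "R03AC02", ]
  expect_true(all(sal$min_age_years == 0))
  expect_true(all(grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", kb$atc_code)))
  expect_true(all(lengths(kb$indication_codes) > 0))
})

test_that("malformed KB files are rejected with named problems", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("atc_code,compound_name,compound_class,min_age_years,indication_prefixes,source_year",
             tmp)
  expect_error(load_label_kb(tmp), "empty")

  writeLines(c(
    "atc_code,compound_name,compound_class,min_age_years,indication_prefixes,source_year",
    "BADCODE,thing,ics,0,J45,2008"
  ), tmp)
  expect_error(load_label_kb(tmp), "malformed ATC")

  writeLines(c(
    "atc_code,compound_name,compound_class,min_age_years,indication_prefixes,source_year",
    "R03BA02,thing,not_a_class,0,J45,2008"
  ), tmp)
  expect_error(load_label_kb(tmp), "unknown compound class")

  writeLines(c(
    "atc_code,compound_name,compound_class,min_age_years,indication_prefixes,source_year",
    "R03BA02,thing,ics,0,,2008"
  ), tmp)
  expect_error(load_label_kb(tmp), "empty indication")

  expect_error(load_label_kb(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("effective label takes the lowest age and the widest indications", {
  recs <- tibble::tibble(
    atc_code = "R03AC04",
    min_age_years = c(4L, 6L),
    indication_codes = list("J45", c("J45", "J44"))
  )
  eff <- resolve_effective_label(recs)
  expect_equal(eff$min_age_years, 4)
  expect_setequal(eff$indication_codes[[1]], c("J44", "J45"))
  expect_equal(eff$n_source_records, 2)

  single <- resolve_effective_label(recs[1, ])
  expect_equal(single$min_age_years, 4)
  expect_equal(single$indication_codes[[1]], "J45")

  zero <- resolve_effective_label(tibble::tibble(
    atc_code = "R03AC02", min_age_years = c(0L, 12L),
    indication_codes = list("J45", "J45")
  ))
  expect_equal(zero$min_age_years, 0)

  expect_error(resolve_effective_label(recs[0, ]), "zero records")
  mixed <- recs
  mixed$atc_code <- c("R03AC04", "R03AC02")
  expect_error(resolve_effective_label(mixed), "mix ATC")
})

test_that("effective-label resolution is idempotent and monotone", {
  set.seed(11)
  pool <- c("J20", "J41", "J42", "J43", "J44", "J45", "J46")
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    recs <- tibble::tibble(
      atc_code = "R03XX99",
      min_age_years = sample(0:18, n, replace = TRUE),
      indication_codes = replicate(n, sample(pool, sample(1:4, 1)),
                                   simplify = FALSE)
    )
    eff <- resolve_effective_label(recs)
    # idempotent: resolving the resolved label returns itself
    again <- resolve_effective_label(eff[, c("atc_code", "min_age_years",
                                             "indication_codes")])
    expect_equal(again$min_age_years, eff$min_age_years)
    expect_setequal(again$indication_codes[[1]], eff$indication_codes[[1]])
    # adding a record can only lower the age and widen the indications
    extra <- tibble::tibble(atc_code = "R03XX99",
                            min_age_years = sample(0:18, 1),
                            indication_codes = list(sample(pool, 2)))
    eff2 <- resolve_effective_label(dplyr::bind_rows(recs, extra))
    expect_lte(eff2$min_age_years, eff$min_age_years)
    expect_true(all(eff$indication_codes[[1]] %in% eff2$indication_codes[[1]]))
  }
})

test_that("ICD matching is prefix-based and normalizes case and dots", {
  expect_true(match_icd("J45.9", "J45"))
  expect_false(match_icd("J20.5", c("J45", "J46")))
  expect_true(match_icd("j459", "J45"))
  expect_true(match_icd("J45.9", "j45"))
  expect_equal(match_icd(c("J45.9", "J20.5", "j46"), c("J45", "J46")),
               c(TRUE, FALSE, TRUE))
  # codes failing the ICD-10 lexical pattern never match, with a warning
  expect_warning(res <- match_icd(c("XX", "J45.9"), "J45"), "ICD-10")
  expect_equal(res, c(FALSE, TRUE))
})

test_that("diagnosis categorization follows the ordered block map", {
  expect_equal(categorize_diagnosis("J20.9"), "Acute bronchitis")
  expect_equal(categorize_diagnosis("J06.9"),
               "Acute upper respiratory infections")
  expect_equal(categorize_diagnosis("J35.1"),
               "Other diseases of upper respiratory tract")
  expect_equal(categorize_diagnosis("J40"), "Bronchitis nec")
  expect_equal(categorize_diagnosis("J84.9"), "Other respiratory diseases")
  expect_equal(categorize_diagnosis("K52.9"), "Non-respiratory")
  # invariant to dot/case formatting
  expect_equal(categorize_diagnosis(c("j209", "J20.9", "J209")),
               rep("Acute bronchitis", 3))
  # total: every code gets exactly one label
  codes <- c("J00", "J06.9", "J20.1", "J21.0", "J30.1", "J40", "J43.9",
             "J44.9", "J45.9", "J98.9", "A09", "Z00")
  labs <- categorize_diagnosis(codes)
  expect_equal(length(labs), length(codes))
  expect_false(any(is.na(labs)))
  # deterministic
  expect_identical(labs, categorize_diagnosis(codes))
})

test_that("category maps with unreachable rows are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("category_label,icd_prefixes",
               "All respiratory,J",
               "Acute bronchitis,J20"), tmp)
  expect_error(load_category_map(tmp), "unreachable")
})
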