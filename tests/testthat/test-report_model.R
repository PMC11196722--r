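test_that("age normalization converts units and rejects abnormal values", {
  expect_equal(normalize_age(24, "months"), 2)
  expect_equal(normalize_age(36, "months"), 3)
  expect_equal(normalize_age(730.5, "days"), 2)
  expect_equal(normalize_age(0, "years"), 0)
  expect_true(is.na(normalize_age(150, "years")))
  expect_true(is.na(normalize_age(-1, "years")))
  expect_true(is.na(normalize_age(30, "unknown")))
  expect_true(is.na(normalize_age(NA, "years")))
})

test_that("age groups honor the printed integer bin edges, flooring fractions", {
  expect_equal(assign_age_group(c(0, 18, 18.9, 19, 39.99, 40, 59.5, 60, 95)),
               c("g0_18", "g0_18", "g0_18", "g19_39", "g19_39",
                 "g40_59", "g40_59", "g60_plus", "g60_plus"))
  expect_equal(assign_age_group(NA), "missing_abnormal")
})

test_that("age groups partition every report into exactly one of five bins", {
  reports <- random_reports(200, seed = 11)
  counts <- table(factor(reports$age_group, levels = AGE_GROUPS))
  expect_equal(sum(counts), nrow(reports))
})

test_that("joined CSV parsing groups rows, normalizes names, handles bad input", {
  reports <- reports_from_rows(list(
    list(case_id = "C1", version = 1, drugs = " cloTRIMazole ",
         events = c("Foetal   death", "rash.")),
    list(case_id = "C1", version = 2),
    list(case_id = "C7", drugs = c("DRUG A", "DRUG B"),
         events = c("E1", "E2", "E3"), age = 24, age_unit = "MON")))
  expect_s3_class(reports, "pv_reports")
  expect_equal(nrow(reports), 3)                    # row groups, pre-dedup
  expect_equal(reports$drugs[[1]], "CLOTRIMAZOLE")
  expect_setequal(reports$events[[1]], c("FOETAL DEATH", "RASH"))
  expect_equal(lengths(reports$drugs[3]), 2, ignore_attr = TRUE)
  expect_equal(lengths(reports$events[3]), 3, ignore_attr = TRUE)
  expect_equal(reports$age_years[3], 2)

  # malformed header names the missing column
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(case_id = "C1", sex = "F"), bad,
                   row.names = FALSE)
  expect_error(read_reports(bad), "version")
  # unparseable age becomes missing with a warning
  expect_warning(
    r <- reports_from_rows(list(list(age = "twenty", age_unit = "YR"))),
    "unparseable")
  expect_true(is.na(r$age_years[1]))
})

test_that("empty source yields an empty collection, not an error", {
  path <- tempfile(fileext = ".csv")
  writeLines("case_id,version,sex,age,age_unit,drugs,events,outcomes", path)
  expect_equal(nrow(read_reports(path)), 0)
})

test_that("FAERS ASCII dialect joins the four files on case_id", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("case_id$version$sex$age$age_cod",
               "C7$1$F$24$MON", "C8$1$M$50$YR"),
             file.path(dir, "DEMO.txt"))
  writeLines(c("case_id$drugname", "C7$Miconazole", "C7$ miconazole",
               "C7$KETOCONAZOLE", "C8$ECONAZOLE"),
             file.path(dir, "DRUG.txt"))
  writeLines(c("case_id$pt", "C7$Rash", "C7$Nausea", "C7$Headache",
               "C8$Dysuria"), file.path(dir, "REAC.txt"))
  writeLines(c("case_id$outc_cod", "C7$HO", "C8$DE"),
             file.path(dir, "OUTC.txt"))
  reports <- read_reports(dir, dialect = "faers_ascii")
  i <- which(reports$case_id == "C7")
  expect_equal(length(reports$drugs[[i]]), 2)       # duplicate drug collapses
  expect_equal(length(reports$events[[i]]), 3)
  expect_equal(reports$age_years[i], 2)
  expect_equal(reports$outcomes[[i]], "hospitalization")
  expect_equal(reports$sex[which(reports$case_id == "C8")], "male")
})

test_that("deduplication keeps the highest version per case, deterministically", {
  r <- reports_from_rows(list(
    list(case_id = "C1", version = 3), list(case_id = "C2", version = 1),
    list(case_id = "C1", version = 2)))
  dd <- deduplicate_reports(r)
  expect_equal(dd$case_id, c("C1", "C2"))
  expect_equal(dd$version[dd$case_id == "C1"], 3)
  # version ties break on the later receipt
  r2 <- reports_from_rows(list(
    list(case_id = "C1", version = 1, drugs = "EARLY"),
    list(case_id = "C1", version = 1, drugs = "LATE")))
  expect_equal(deduplicate_reports(r2)$drugs[[1]], "LATE")
  # idempotent on arbitrary generated input
  for (seed in 1:5) {
    rr <- random_reports(60, seed = seed)
    rr$case_id <- sample(rr$case_id, nrow(rr), replace = TRUE)
    once <- deduplicate_reports(rr)
    expect_identical(deduplicate_reports(once), once)
    expect_equal(nrow(once), length(unique(rr$case_id)))
  }
})

test_that("filtering matches criteria, strips event patterns, never grows", {
  r <- reports_from_rows(list(
    list(sex = "female", events = c("NAUSEA", "PRODUCT ISSUE")),
    list(sex = "female", events = "PRODUCT QUALITY ISSUE"),
    list(sex = "male", events = "NAUSEA")))
  expect_equal(nrow(filter_reports(r, report_criteria(sex = "female"))), 2)
  expect_identical(filter_reports(r, report_criteria())$case_id, r$case_id)
  out <- filter_reports(r, report_criteria(exclude_events = "PRODUCT"))
  expect_equal(nrow(out), 2)                       # all-excluded report drops
  expect_equal(out$events[[1]], "NAUSEA")
  for (seed in 1:5) {
    rr <- random_reports(50, seed = seed + 20)
    crit <- report_criteria(sex = "female", drug = "DRUG A")
    expect_lte(nrow(filter_reports(rr, crit)), nrow(rr))
  }
})

test_that("canonical CSV writing round-trips a collection", {
  reports <- deduplicate_reports(random_reports(80, seed = 31))
  path <- tempfile(fileext = ".csv")
  write_reports(reports, path)
  back <- read_reports(path)
  expect_equal(back$case_id, reports$case_id)
  expect_equal(back$drugs, reports$drugs)
  expect_equal(back$events, reports$events)
  expect_equal(back$outcomes, reports$outcomes)
  expect_equal(back$age_years, reports$age_years, tolerance = 1e-12)
  expect_equal(back$age_group, reports$age_group)
  # and writing the re-parsed collection is byte-identical
  path2 <- tempfile(fileext = ".csv")
  write_reports(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
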