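# Shared fixture builders. All fixtures are constructed in code; report
# collections go through the public CSV parser so the reader is exercised
# everywhere.

# Build a pv_reports collection by writing and re-reading the canonical CSV.
# rows: list of lists with any of case_id, version, sex, age, age_unit,
# drugs, events, outcomes (drugs/events/outcomes as character vectors).
reports_from_rows <- function(rows) {
  def <- list(case_id = NA, version = 1, sex = "female", age = 30,
              age_unit = "YR", drugs = "DRUG A", events = "EVENT X",
              outcomes = character(0))
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- utils::modifyList(def, rows[[i]])
    data.frame(case_id = ifelse(is.na(r$case_id), sprintf("C%03d", i),
                                r$case_id),
               version = r$version, sex = r$sex,
               age = ifelse(is.na(r$age), "", as.character(r$age)),
               age_unit = r$age_unit,
               drugs = paste(r$drugs, collapse = ";"),
               events = paste(r$events, collapse = ";"),
               outcomes = paste(r$outcomes, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  on.exit(unlink(path))
  read_reports(path, dialect = "joined_csv")
}

# Independent brute-force oracle for contingency cells: a double loop over
# reports and the four membership combinations.
brute_contingency <- function(reports, drug, event) {
  a <- b <- c <- d <- 0
  for (i in seq_len(nrow(reports))) {
    hd <- drug %in% reports$drugs[[i]]
    he <- event %in% reports$events[[i]]
    if (hd && he) a <- a + 1
    else if (hd) b <- b + 1
    else if (he) c <- c + 1
    else d <- d + 1
  }
  c(a = a, b = b, c = c, d = d)
}

pkg_extdata <- function(...) system.file("extdata", ..., package = "pvsignal")

mini_hierarchy <- function() read_hierarchy(pkg_extdata("meddra_mini.tsv"))

# Random small report set for property tests (built directly, not via the
# generator, so generator bugs cannot mask parser/statistic bugs).
random_reports <- function(n, seed, n_drugs = 4, n_events = 8) {
  set.seed(seed)
  drugs <- sprintf("DRUG %s", LETTERS[seq_len(n_drugs)])
  events <- sprintf("EVENT %d", seq_len(n_events))
  rows <- lapply(seq_len(n), function(i) {
    list(case_id = sprintf("R%04d", i),
         sex = sample(c("female", "male", "unknown"), 1),
         age = sample(c(NA, 1:90), 1),
         drugs = sample(drugs, sample.int(min(3, n_drugs), 1)),
         events = sample(events, sample.int(min(4, n_events), 1)),
         outcomes = sample(c("DE", "HO", "OT"), sample.int(3, 1) - 1))
  })
  reports_from_rows(rows)
}
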