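#' @title Spontaneous report collections
#' @description
#' A report collection is a data frame of class `pv_reports` with one row per
#' case-version: columns `case_id`, `version`, `sex`, `age_value`,
#' `age_unit`, `age_years`, `age_group`, `receipt_order` and the list-columns
#' `drugs`, `events`, `outcomes` (normalized, sorted, unique term sets).
#' @name pv_reports
NULL

REPORT_COLUMNS <- c("case_id", "version", "sex", "age_value", "age_unit",
                    "age_years", "age_group", "drugs", "events", "outcomes",
                    "receipt_order")

new_reports <- function(df) {
  df <- df[REPORT_COLUMNS]
  rownames(df) <- NULL
  class(df) <- c("pv_reports", "data.frame")
  df
}

#' @export
print.pv_reports <- function(x, ...) {
  cat(sprintf("<pv_reports> %d case-version rows, %d unique cases\n",
              nrow(x), length(unique(x$case_id))))
  cat(sprintf("  drugs: %d distinct; events: %d distinct\n",
              length(unique(unlist(x$drugs))),
              length(unique(unlist(x$events)))))
  invisible(x)
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("F", "FEMALE")] <- "female"
  out[x %in% c("M", "MALE")] <- "male"
  out
}

normalize_age_unit <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("YR", "YEAR", "YEARS", "Y")] <- "years"
  out[x %in% c("MON", "MONTH", "MONTHS", "MO")] <- "months"
  out[x %in% c("DY", "DAY", "DAYS", "D")] <- "days"
  out
}

#' Convert a reported age to years
#'
#' Total function mapping an (age value, unit) pair to age in years. Months
#' divide by 12 and days by 365.25; an unknown unit or missing value yields
#' `NA`. Ages below 0 or above 120 years are treated as abnormal and also
#' yield `NA`, so downstream binning puts them in the abnormal-or-missing
#' group.
#'
#' @param age_value Numeric vector of reported ages (may contain `NA`).
#' @param age_unit Character vector: `"years"`, `"months"`, `"days"` or
#'   `"unknown"` (recycled if length 1).
#' @return Numeric vector of ages in years, `NA` where missing or abnormal.
#' @examples
#' normalize_age(36, "months")   # 3
#' normalize_age(150, "years")   # NA (abnormal)
#' @export
normalize_age <- function(age_value, age_unit) {
  age_value <- as.numeric(age_value)
  if (length(age_unit) == 1L) age_unit <- rep(age_unit, length(age_value))
  stopifnot(length(age_unit) == length(age_value))
  div <- c(years = 1, months = 12, days = 365.25)[age_unit]
  out <- age_value / div            # NA where unit unknown (div NA)
  out[is.na(age_value)] <- NA_real_
  out[!is.na(out) & (out < 0 | out > 120)] <- NA_real_
  unname(out)
}

#' Assign an age in years to a reporting age group
#'
#' Fractional ages floor to whole years before binning, so the printed
#' integer bin edges 0--18, 19--39, 40--59, >= 60 are honored exactly
#' (18.9 years falls in 0--18). Missing ages go to `missing_abnormal`.
#'
#' @param age_years Numeric vector of ages in years (`NA` allowed).
#' @return Character vector drawn from [AGE_GROUPS].
#' @export
assign_age_group <- function(age_years) {
  yrs <- floor(as.numeric(age_years))
  out <- rep("missing_abnormal", length(yrs))
  ok <- !is.na(yrs) & yrs >= 0 & yrs <= 120
  out[ok & yrs <= 18] <- "g0_18"
  out[ok & yrs >= 19 & yrs <= 39] <- "g19_39"
  out[ok & yrs >= 40 & yrs <= 59] <- "g40_59"
  out[ok & yrs >= 60] <- "g60_plus"
  out
}

# Assemble a pv_reports object from per-case-version vectors; applies age
# normalization, binning, and the nonempty drugs/events invariant.
assemble_reports <- function(case_id, version, sex, age_value, age_unit,
                             drugs, events, outcomes, n_bad_age = 0L) {
  age_years <- normalize_age(age_value, age_unit)
  df <- data.frame(case_id = as.character(case_id),
                   version = as.integer(version),
                   sex = sex, age_value = as.numeric(age_value),
                   age_unit = age_unit, age_years = age_years,
                   age_group = assign_age_group(age_years),
                   receipt_order = seq_along(case_id),
                   stringsAsFactors = FALSE)
  df$drugs <- drugs
  df$events <- events
  df$outcomes <- outcomes
  empty <- lengths(df$drugs) == 0L | lengths(df$events) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d report(s) with no drug or no event", sum(empty)))
    df <- df[!empty, , drop = FALSE]
    df$receipt_order <- seq_len(nrow(df))
  }
  if (n_bad_age > 0)
    warning(sprintf("%d unparseable age value(s) treated as missing", n_bad_age))
  new_reports(df)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

parse_numeric_ages <- function(x) {
  raw <- trimws(as.character(x))
  val <- suppressWarnings(as.numeric(raw))
  bad <- is.na(val) & !is.na(raw) & nzchar(raw) & toupper(raw) != "NA"
  list(value = val, n_bad = sum(bad))
}

decode_outcomes <- function(lst) {
  lapply(lst, function(v) {
    v <- toupper(v)
    dec <- ifelse(v %in% names(OUTCOME_CODES), OUTCOME_CODES[v],
                  ifelse(tolower(v) %in% OUTCOME_LEVELS, tolower(v), NA))
    sort(unique(dec[!is.na(dec)]))
  })
}

#' Read spontaneous adverse-event reports
#'
#' Parses one of two supported dialects into a [pv_reports] collection.
#'
#' * `joined_csv` (canonical): one row per case-version with columns
#'   `case_id, version, sex, age, age_unit, drugs, events, outcomes`;
#'   `drugs`/`events` are semicolon-joined names, `outcomes` semicolon-joined
#'   codes (`DE`, `DS`, `HO`, `LT`, `OT`).
#' * `faers_ascii`: four `$`-delimited files in a directory —
#'   `DEMO` (`case_id$version$sex$age$age_cod`), `DRUG` (`case_id$drugname`),
#'   `REAC` (`case_id$pt`), `OUTC` (`case_id$outc_cod`) — joined on
#'   `case_id`.
#'
#' Drug and event names are uppercased with whitespace collapsed; within a
#' case each term counts once (set semantics). Unparseable ages become
#' missing with a warning. An empty source yields an empty collection.
#'
#' @param path For `joined_csv`, the CSV file; for `faers_ascii`, a directory
#'   containing files whose names start with `DEMO`, `DRUG`, `REAC`, `OUTC`.
#' @param dialect `"joined_csv"` (default) or `"faers_ascii"`.
#' @return A [pv_reports] data frame (one row per case-version; call
#'   [deduplicate_reports()] before analysis).
#' @export
read_reports <- function(path, dialect = c("joined_csv", "faers_ascii")) {
  dialect <- match.arg(dialect)
  if (dialect == "joined_csv") read_reports_csv(path) else read_reports_faers(path)
}

read_reports_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  require_columns(df, c("case_id", "version", "sex", "age", "age_unit",
                        "drugs", "events", "outcomes"), "joined_csv dialect")
  if (nrow(df) == 0L)
    return(assemble_reports(character(), integer(), character(), numeric(),
                            character(), list(), list(), list()))
  ages <- parse_numeric_ages(df$age)
  assemble_reports(df$case_id, as.integer(df$version),
                   normalize_sex(df$sex), ages$value,
                   normalize_age_unit(df$age_unit),
                   split_terms(df$drugs), split_terms(df$events),
                   decode_outcomes(split_terms(df$outcomes)),
                   n_bad_age = ages$n_bad)
}

read_faers_file <- function(dir, prefix, cols) {
  files <- list.files(dir, pattern = paste0("^", prefix), full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) != 1L)
    stop(sprintf("faers_ascii dialect: expected exactly one %s* file in %s",
                 prefix, dir), call. = FALSE)
  df <- utils::read.table(files[1], sep = "$", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  names(df) <- tolower(names(df))
  require_columns(df, cols, sprintf("faers_ascii %s file", prefix))
  df
}

read_reports_faers <- function(path) {
  demo <- read_faers_file(path, "DEMO", c("case_id", "version", "sex", "age", "age_cod"))
  drug <- read_faers_file(path, "DRUG", c("case_id", "drugname"))
  reac <- read_faers_file(path, "REAC", c("case_id", "pt"))
  outc <- read_faers_file(path, "OUTC", c("case_id", "outc_cod"))
  if (nrow(demo) == 0L)
    return(assemble_reports(character(), integer(), character(), numeric(),
                            character(), list(), list(), list()))
  gather <- function(df, col) {
    s <- split(normalize_terms(df[[col]]), df$case_id)
    lapply(s, function(v) sort(unique(v[nzchar(v)])))
  }
  drugs_by <- gather(drug, "drugname")
  reac_by <- gather(reac, "pt")
  outc_by <- gather(outc, "outc_cod")
  pick <- function(byid, id) if (is.null(byid[[id]])) character(0) else byid[[id]]
  ages <- parse_numeric_ages(demo$age)
  assemble_reports(demo$case_id, as.integer(demo$version),
                   normalize_sex(demo$sex), ages$value,
                   normalize_age_unit(demo$age_cod),
                   lapply(demo$case_id, pick, byid = drugs_by),
                   lapply(demo$case_id, pick, byid = reac_by),
                   decode_outcomes(lapply(demo$case_id, pick, byid = outc_by)),
                   n_bad_age = ages$n_bad)
}

#' Deduplicate case versions
#'
#' Keeps exactly one row per `case_id`: the highest `version`, with ties
#' broken by the larger `receipt_order` (the later file position). The FAERS
#' convention is that later case versions supersede earlier ones. Output is
#' sorted by `case_id` so results are deterministic. Idempotent.
#'
#' @param reports A [pv_reports] collection.
#' @return A [pv_reports] collection with unique `case_id`s.
#' @export
deduplicate_reports <- function(reports) {
  if (nrow(reports) == 0L) return(reports)
  ord <- order(reports$case_id, reports$version, reports$receipt_order)
  df <- reports[ord, , drop = FALSE]
  keep <- !duplicated(df$case_id, fromLast = TRUE)
  new_reports(df[keep, , drop = FALSE])
}

#' Filtering criteria for report collections
#'
#' All criteria are optional; an empty criteria object is the identity
#' filter. `exclude_events` holds normalized substring patterns (for example
#' product-problem terms): matching PTs are removed from each report's event
#' set, and reports whose event set becomes empty are dropped.
#'
#' @param sex Optional: keep only reports with this sex
#'   (`"female"`, `"male"`, `"unknown"`).
#' @param drug Optional generic name; keep only reports mentioning it.
#' @param exclude_events Character vector of substring patterns to strip
#'   from event sets.
#' @return An object of class `pv_criteria`.
#' @export
report_criteria <- function(sex = NULL, drug = NULL, exclude_events = character()) {
  if (!is.null(sex)) sex <- match.arg(sex, c("female", "male", "unknown"))
  structure(list(sex = sex,
                 drug = if (is.null(drug)) NULL else normalize_terms(drug),
                 exclude_events = normalize_terms(exclude_events)),
            class = "pv_criteria")
}

#' Filter a report collection
#'
#' Applies a [report_criteria()] object: sex restriction, required drug, and
#' event-pattern exclusion (see [report_criteria()]). Returns a new
#' collection; the input is not modified.
#'
#' @param reports A [pv_reports] collection.
#' @param criteria A `pv_criteria` object.
#' @return The filtered [pv_reports] collection.
#' @export
filter_reports <- function(reports, criteria = report_criteria()) {
  stopifnot(inherits(criteria, "pv_criteria"))
  df <- reports
  if (!is.null(criteria$sex)) df <- df[df$sex == criteria$sex, , drop = FALSE]
  if (!is.null(criteria$drug))
    df <- df[vapply(df$drugs, function(v) criteria$drug %in% v, logical(1)), ,
             drop = FALSE]
  pats <- criteria$exclude_events
  if (length(pats) && nrow(df)) {
    df$events <- lapply(df$events, function(ev) {
      hit <- vapply(ev, function(e) any(vapply(pats, grepl, logical(1),
                                               x = e, fixed = TRUE)),
                    logical(1))
      ev[!hit]
    })
    df <- df[lengths(df$events) > 0L, , drop = FALSE]
  }
  new_reports(df)
}

#' Write reports in the canonical joined-CSV dialect
#'
#' Emits the `joined_csv` dialect with a stable column order, sorted term
#' sets and `\n` line endings, so identical collections serialize to
#' byte-identical files and `read_reports()` round-trips.
#'
#' @param reports A [pv_reports] collection.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  code_of <- setNames(names(OUTCOME_CODES), OUTCOME_CODES)
  fmt_age <- function(x) ifelse(is.na(x), "",
                                format(x, digits = 15, trim = TRUE,
                                       scientific = FALSE))
  out <- data.frame(case_id = reports$case_id,
                    version = reports$version,
                    sex = reports$sex,
                    age = fmt_age(reports$age_value),
                    age_unit = reports$age_unit,
                    drugs = join_terms(reports$drugs),
                    events = join_terms(reports$events),
                    outcomes = vapply(reports$outcomes, function(v)
                      paste(code_of[v], collapse = ";"), character(1)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, eol = "\n",
                   na = "")
  invisible(path)
}
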