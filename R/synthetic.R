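#' @title Synthetic spontaneous-report generator
#' @description
#' Generates FAERS-like report collections with known ground truth.
#' Generative model, per case: sex and age group are drawn from configured
#' mixtures (an age value, possibly expressed in months for infants or left
#' missing/abnormal, is then drawn inside the bin); each drug is an
#' independent Bernoulli draw, resampled until at least one drug is present;
#' each event is an independent Bernoulli draw whose odds are multiplied by
#' the rate ratio `lambda` of every planted (drug, event) association whose
#' drug is present (and whose age restriction, if any, matches), resampled
#' until at least one event is present; outcomes are independent Bernoulli
#' draws. A configurable fraction of cases additionally emits an earlier
#' duplicate version of itself, exercising deduplication.
#'
#' Planting acts on the odds scale, so the true report-level odds ratio of
#' a planted pair equals `lambda` exactly — including under the
#' nonempty-drug and nonempty-event rejection steps, because the rejection
#' inflates the event odds by the same factor in the drug and no-drug arms.
#' [expected_table()] returns the exact expected cell counts under the full
#' model (rejection conditioning included) by enumerating drug subsets and
#' age groups.
#' @name synthetic_data
NULL

default_drugs <- function() {
  c(CLOTRIMAZOLE = 0.2259, ECONAZOLE = 0.0491,
    KETOCONAZOLE = 0.1904, MICONAZOLE = 0.5346)
}

default_events <- function() {
  c(NAUSEA = 0.12, HEADACHE = 0.10, RASH = 0.09, PRURITUS = 0.08,
    `VULVOVAGINAL BURNING SENSATION` = 0.07, DIZZINESS = 0.06,
    VOMITING = 0.06, DIARRHOEA = 0.05, FATIGUE = 0.05,
    `APPLICATION SITE BURNING` = 0.04, URTICARIA = 0.03,
    `ACUTE KIDNEY INJURY` = 0.02, `RENAL FAILURE` = 0.015,
    HAEMATURIA = 0.012, `CHRONIC KIDNEY DISEASE` = 0.012, DYSURIA = 0.012,
    `ABORTION SPONTANEOUS` = 0.010, `FOETAL DEATH` = 0.006,
    `SEPSIS NEONATAL` = 0.003,
    `BLADDER TRANSITIONAL CELL CARCINOMA` = 0.002)
}

default_planted <- function() {
  list(
    list(drug = "CLOTRIMAZOLE", event = "BLADDER TRANSITIONAL CELL CARCINOMA",
         lambda = 20, age_group = "g60_plus"),
    list(drug = "ECONAZOLE", event = "ABORTION SPONTANEOUS",
         lambda = 10, age_group = "g19_39"),
    list(drug = "MICONAZOLE", event = "HAEMATURIA", lambda = 8,
         age_group = NULL)
  )
}

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the study conditions of a female-dominant FAERS extract
#' for the four topical imidazole antifungals: drug marginals equal to the
#' published per-drug report shares, age-bin masses from the published age
#' table, outcome probabilities near the published severity rates, and a
#' small set of planted drug--event associations with known rate ratios.
#'
#' @param n_reports Number of unique cases.
#' @param drugs Named numeric vector: per-drug marginal probability.
#' @param events Named numeric vector: per-event baseline probability.
#' @param planted List of `list(drug, event, lambda, age_group = NULL)`;
#'   `lambda > 0` multiplies the event's baseline odds in reports carrying
#'   the drug (restricted to one age group when given).
#' @param sex_probs Named probabilities over `female`, `male`, `unknown`.
#' @param age_probs Named probabilities over [AGE_GROUPS] (normalized).
#' @param outcome_probs Named per-outcome probabilities over
#'   [OUTCOME_LEVELS].
#' @param duplicate_fraction Probability a case also emits an earlier
#'   version row.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated `pv_synth_config` list.
#' @export
synth_config <- function(n_reports = 2000,
                         drugs = default_drugs(),
                         events = default_events(),
                         planted = default_planted(),
                         sex_probs = c(female = 0.90, male = 0.07,
                                       unknown = 0.03),
                         age_probs = c(g0_18 = 0.0206, g19_39 = 0.2172,
                                       g40_59 = 0.2174, g60_plus = 0.1951,
                                       missing_abnormal = 0.3497),
                         outcome_probs = c(death = 0.055, disability = 0.026,
                                           hospitalization = 0.185,
                                           life_threatening = 0.053,
                                           other = 0.30),
                         duplicate_fraction = 0.1,
                         seed = 1L) {
  if (!all(AGE_GROUPS %in% names(age_probs)))
    stop("synthetic config error: age_probs must cover all age groups",
         call. = FALSE)
  cfg <- list(n_reports = as.integer(n_reports), drugs = drugs,
              events = events, planted = planted, sex_probs = sex_probs,
              age_probs = age_probs[AGE_GROUPS],
              outcome_probs = outcome_probs,
              duplicate_fraction = duplicate_fraction, seed = as.integer(seed))
  names(cfg$drugs) <- normalize_terms(names(drugs))
  names(cfg$events) <- normalize_terms(names(events))
  validate_synth_config(cfg)
  cfg$age_probs <- cfg$age_probs / sum(cfg$age_probs)
  cfg$sex_probs <- cfg$sex_probs / sum(cfg$sex_probs)
  structure(cfg, class = "pv_synth_config")
}

validate_synth_config <- function(cfg) {
  probs <- c(cfg$drugs, cfg$events, cfg$sex_probs, cfg$age_probs,
             cfg$outcome_probs, cfg$duplicate_fraction)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("synthetic config error: probabilities must lie in [0, 1]",
         call. = FALSE)
  if (cfg$n_reports <= 0)
    stop("synthetic config error: n_reports must be positive", call. = FALSE)
  if (any(names(cfg$age_probs) != AGE_GROUPS) || any(is.na(cfg$age_probs)))
    stop("synthetic config error: age_probs must cover all age groups",
         call. = FALSE)
  for (p in cfg$planted) {
    if (!p$drug %in% names(cfg$drugs))
      stop(sprintf("synthetic config error: planted drug %s not in vocabulary",
                   p$drug), call. = FALSE)
    if (!p$event %in% names(cfg$events))
      stop(sprintf("synthetic config error: planted event %s not in vocabulary",
                   p$event), call. = FALSE)
    if (is.null(p$lambda) || p$lambda <= 0)
      stop("synthetic config error: planted lambda must be > 0", call. = FALSE)
    if (!is.null(p$age_group) && !p$age_group %in% AGE_GROUPS)
      stop("synthetic config error: unknown planted age_group", call. = FALSE)
  }
  invisible(cfg)
}

# Event probabilities given a drug-presence matrix (n x K logical) and the
# age-group vector: baseline odds times the lambda of every applicable
# planted association, capped at probability 1 by construction of the odds
# transform.
event_prob_matrix <- function(cfg, drug_mat, age_group) {
  n <- nrow(drug_mat)
  base <- cfg$events
  odds <- matrix(rep(base / (1 - base), each = n), nrow = n)
  colnames(odds) <- names(base)
  for (p in cfg$planted) {
    applies <- drug_mat[, p$drug]
    if (!is.null(p$age_group)) applies <- applies & age_group == p$age_group
    odds[applies, p$event] <- odds[applies, p$event] * p$lambda
  }
  odds / (1 + odds)
}

# Draw an n x m Bernoulli matrix row-rejected to have >= 1 success per row.
draw_nonempty <- function(prob, colnames_) {
  n <- nrow(prob)
  out <- matrix(runif(length(prob)) < prob, nrow = n)
  redo <- which(rowSums(out) == 0L)
  while (length(redo)) {
    sub <- prob[redo, , drop = FALSE]
    out[redo, ] <- runif(length(sub)) < sub
    redo <- redo[rowSums(out[redo, , drop = FALSE]) == 0L]
  }
  colnames(out) <- colnames_
  out
}

sample_age <- function(age_group) {
  n <- length(age_group)
  lo <- c(g0_18 = 0, g19_39 = 19, g40_59 = 40, g60_plus = 60)
  hi <- c(g0_18 = 19, g19_39 = 40, g40_59 = 60, g60_plus = 95)
  yrs <- rep(NA_real_, n)
  known <- age_group %in% names(lo)
  yrs[known] <- lo[age_group[known]] +
    runif(sum(known)) * (hi[age_group[known]] - lo[age_group[known]])
  # the missing/abnormal bucket: mostly absent ages, some out-of-range ones
  mab <- which(!known)
  abn <- mab[runif(length(mab)) < 0.2]
  value <- yrs; unit <- ifelse(known, "years", "unknown")
  value[abn] <- 121 + runif(length(abn)) * 79
  unit[abn] <- "years"
  # infants often have ages reported in months
  mon <- which(!is.na(yrs) & yrs < 3 & runif(n) < 0.5)
  value[mon] <- yrs[mon] * 12
  unit[mon] <- "months"
  list(value = value, unit = unit)
}

#' Generate a synthetic report collection with ground truth
#'
#' Draws `n_reports` unique cases under the configured generative model
#' (see [synthetic_data]) plus earlier duplicate versions for a
#' `duplicate_fraction` share of cases. Identical config and seed give an
#' identical collection. The accompanying truth table holds, for every
#' (drug, event) pair, the analytic expected 2x2 cells, the implied true
#' odds ratio, and the configured `lambda`.
#'
#' @param config A [synth_config()] object.
#' @return List with `reports` (a [pv_reports] collection of raw
#'   case-version rows; run [deduplicate_reports()] before analysis) and
#'   `truth` (data frame `drug`, `event`, `lambda`, `age_group`,
#'   `exp_a`, `exp_b`, `exp_c`, `exp_d`, `true_or`).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "pv_synth_config"))
  validate_synth_config(config)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  n <- config$n_reports
  sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
  age_group <- sample(AGE_GROUPS, n, TRUE, config$age_probs)
  age <- sample_age(age_group)

  K <- length(config$drugs)
  drug_mat <- draw_nonempty(matrix(rep(config$drugs, each = n), nrow = n),
                            names(config$drugs))
  p_ev <- event_prob_matrix(config, drug_mat, age_group)
  ev_mat <- matrix(runif(length(p_ev)) < p_ev, nrow = n)
  redo <- which(rowSums(ev_mat) == 0L)
  while (length(redo)) {
    sub <- p_ev[redo, , drop = FALSE]
    ev_mat[redo, ] <- runif(length(sub)) < sub
    redo <- redo[rowSums(ev_mat[redo, , drop = FALSE]) == 0L]
  }
  colnames(ev_mat) <- names(config$events)

  out_mat <- matrix(runif(n * length(config$outcome_probs)) <
                      rep(config$outcome_probs, each = n), nrow = n)
  colnames(out_mat) <- names(config$outcome_probs)

  drugs <- apply(drug_mat, 1, function(r) names(config$drugs)[r],
                 simplify = FALSE)
  events <- apply(ev_mat, 1, function(r) names(config$events)[r],
                  simplify = FALSE)
  outcomes <- apply(out_mat, 1, function(r)
    sort(names(config$outcome_probs)[r]), simplify = FALSE)

  case_id <- sprintf("CASE%06d", seq_len(n))
  dup <- runif(n) < config$duplicate_fraction
  version <- ifelse(dup, 2L, 1L)

  idx <- c(which(dup), seq_len(n))        # earlier versions received first
  ver <- c(rep(1L, sum(dup)), version)
  reports <- assemble_reports(case_id[idx], ver, sex[idx], age$value[idx],
                              age$unit[idx], drugs[idx], events[idx],
                              outcomes[idx])

  truth <- truth_table(config)
  list(reports = reports, truth = truth)
}

# Enumerate nonempty drug subsets with probabilities conditional on >= 1
# drug; rows are subsets, columns drugs.
drug_subsets <- function(p_drugs) {
  K <- length(p_drugs)
  if (K > 16) stop("expected_table supports at most 16 drugs", call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), K)))
  colnames(grid) <- names(p_drugs)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  w <- apply(grid, 1, function(s)
    prod(ifelse(s, p_drugs, 1 - p_drugs)))
  list(subsets = grid, w = w / sum(w))
}

#' Analytic expected 2x2 table under the generative model
#'
#' Closed-form expected cell counts `n * P(cell)` for a (drug, event) pair,
#' computed exactly by enumerating drug subsets and age groups and applying
#' the nonempty-drug and nonempty-event conditioning the generator uses.
#' Serves as the oracle for parameter-recovery tests: for a pair planted
#' without age restriction the expected-cell odds ratio equals `lambda`
#' exactly.
#'
#' @param config A [synth_config()] object.
#' @param drug,event Pair to evaluate (must be in the config vocabularies).
#' @return List: `a`, `b`, `c`, `d` (real-valued expected counts), `N`,
#'   `true_or`.
#' @export
expected_table <- function(config, drug, event) {
  stopifnot(inherits(config, "pv_synth_config"))
  drug <- normalize_terms(drug); event <- normalize_terms(event)
  if (!drug %in% names(config$drugs))
    stop(sprintf("unknown drug: %s", drug), call. = FALSE)
  if (!event %in% names(config$events))
    stop(sprintf("unknown event: %s", event), call. = FALSE)
  ds <- drug_subsets(config$drugs)
  cells <- c(a = 0, b = 0, c = 0, d = 0)
  for (gi in seq_along(AGE_GROUPS)) {
    g <- AGE_GROUPS[gi]
    wg <- config$age_probs[[g]]
    if (wg == 0) next
    for (si in seq_len(nrow(ds$subsets))) {
      s <- ds$subsets[si, ]
      w <- ds$w[si] * wg
      # per-event probabilities for this subset and age group
      odds <- config$events / (1 - config$events)
      for (p in config$planted) {
        if (s[[p$drug]] && (is.null(p$age_group) || p$age_group == g))
          odds[[p$event]] <- odds[[p$event]] * p$lambda
      }
      pe <- odds / (1 + odds)
      q <- 1 - prod(1 - pe)                # P(>= 1 event | subset, group)
      p_event <- pe[[event]] / q           # conditional on nonempty events
      if (s[[drug]]) {
        cells["a"] <- cells["a"] + w * p_event
        cells["b"] <- cells["b"] + w * (1 - p_event)
      } else {
        cells["c"] <- cells["c"] + w * p_event
        cells["d"] <- cells["d"] + w * (1 - p_event)
      }
    }
  }
  cells <- cells * config$n_reports
  list(a = unname(cells["a"]), b = unname(cells["b"]),
       c = unname(cells["c"]), d = unname(cells["d"]),
       N = config$n_reports,
       true_or = unname((cells["a"] * cells["d"]) /
                          (cells["b"] * cells["c"])))
}

truth_table <- function(config) {
  planted_key <- vapply(config$planted, function(p)
    paste(p$drug, p$event, sep = "\r"), character(1))
  rows <- list()
  for (dg in names(config$drugs)) for (ev in names(config$events)) {
    et <- expected_table(config, dg, ev)
    hit <- match(paste(dg, ev, sep = "\r"), planted_key)
    rows[[length(rows) + 1L]] <- data.frame(
      drug = dg, event = ev,
      lambda = if (is.na(hit)) 1 else config$planted[[hit]]$lambda,
      age_group = if (is.na(hit) || is.null(config$planted[[hit]]$age_group))
        NA_character_ else config$planted[[hit]]$age_group,
      exp_a = et$a, exp_b = et$b, exp_c = et$c, exp_d = et$d,
      true_or = et$true_or, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference report collection with the published marginal counts
#'
#' Builds, deterministically and in code, a fixed collection of 9985
#' single-drug female reports whose per-drug, per-age-group and
#' per-severity-outcome marginal counts equal the published FAERS summary
#' for the four imidazole antifungals (clotrimazole 2256, econazole 490,
#' ketoconazole 1901, miconazole 5338; severe total 3187). Used as a
#' packaged fixture: [severity_summary()] on this collection recomputes the
#' published shares and severity percentages exactly.
#'
#' @return A deduplicated [pv_reports] collection of 9985 reports.
#' @export
reference_reports <- function() {
  drugs <- c("CLOTRIMAZOLE", "ECONAZOLE", "KETOCONAZOLE", "MICONAZOLE")
  # per-drug age-group counts (g0_18, g19_39, g40_59, g60_plus, missing)
  age_counts <- rbind(
    CLOTRIMAZOLE = c(36, 392, 661, 464, 703),
    ECONAZOLE   = c(0, 50, 28, 286, 126),
    KETOCONAZOLE = c(15, 288, 639, 483, 476),
    MICONAZOLE  = c(155, 1439, 843, 715, 2186))
  # per-drug severity-outcome counts (death, disability, hosp., life-thr.)
  out_counts <- rbind(
    CLOTRIMAZOLE = c(339, 102, 756, 210),
    ECONAZOLE   = c(109, 19, 205, 32),
    KETOCONAZOLE = c(53, 78, 391, 153),
    MICONAZOLE  = c(45, 63, 500, 132))
  age_years_rep <- c(g0_18 = 10, g19_39 = 30, g40_59 = 50, g60_plus = 70,
                     missing_abnormal = NA_real_)
  rows_drug <- character(0); rows_age <- character(0)
  for (dg in drugs) {
    rows_drug <- c(rows_drug, rep(dg, sum(age_counts[dg, ])))
    rows_age <- c(rows_age, rep(AGE_GROUPS, age_counts[dg, ]))
  }
  n <- length(rows_drug)
  outcomes <- vector("list", n)
  outcomes[] <- list(character(0))
  pos <- 1L
  for (dg in drugs) {
    n_dg <- sum(age_counts[dg, ])
    oc <- rep(OUTCOME_LEVELS[1:4], out_counts[dg, ])
    idx <- pos + seq_along(oc) - 1L
    outcomes[idx] <- as.list(oc)
    pos <- pos + n_dg
  }
  assemble_reports(case_id = sprintf("REF%05d", seq_len(n)),
                   version = rep(1L, n), sex = rep("female", n),
                   age_value = unname(age_years_rep[rows_age]),
                   age_unit = ifelse(is.na(age_years_rep[rows_age]),
                                     "unknown", "years"),
                   drugs = as.list(rows_drug),
                   events = rep(list("ADVERSE DRUG REACTION"), n),
                   outcomes = outcomes)
}
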