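#' @title Descriptive and stratified summaries
#' @description
#' Reproduces the standard descriptive outputs of a spontaneous-report
#' analysis: per-drug report counts and shares, severity-outcome and
#' age-group breakdowns, primary-SOC distributions of the detected signals,
#' ranking of signals by interval lower bound, and the per-drug,
#' per-age-group stratified signal table.
#' @name summarize
NULL

#' Descriptive summary of a report collection
#'
#' For each drug (and in total): report counts with percentages of the
#' grand total (2 decimals, half-up), age-group counts, counts per severity
#' outcome, and the severe fraction. A report is "severe" when it carries at
#' least one of death, disability, hospitalization or life-threatening.
#' Severe fractions per drug are reported with integer-rounded percentages
#' (the conventional `365/490 (74%)` style); all other percentages use the
#' grand total as denominator.
#'
#' @param reports A deduplicated [pv_reports] collection.
#' @param drug_list Character vector of drugs to tabulate (normalized
#'   internally). A listed drug absent from the data yields a zero row.
#' @return A `pv_severity_summary` list: `n_total`, `reports` (drug, n,
#'   pct), `age` (drug x age-group long table), `outcomes` (drug x outcome
#'   long table), `severe` (drug, n_severe, n, pct_of_total, pct_int).
#' @export
severity_summary <- function(reports, drug_list) {
  drug_list <- normalize_terms(drug_list)
  n_total <- nrow(reports)
  if (n_total == 0L) stop("empty report collection", call. = FALSE)
  has_drug <- function(dg) vapply(reports$drugs, function(v) dg %in% v,
                                  logical(1))
  severe <- vapply(reports$outcomes,
                   function(v) any(v %in% SEVERE_OUTCOMES), logical(1))
  groups <- c(total = list(rep(TRUE, n_total)),
              setNames(lapply(drug_list, has_drug), drug_list))

  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    n <- sum(sel)
    age_n <- vapply(AGE_GROUPS, function(ag)
      sum(sel & reports$age_group == ag), numeric(1))
    out_n <- vapply(OUTCOME_LEVELS[1:4], function(oc)
      sum(sel & vapply(reports$outcomes, function(v) oc %in% v, logical(1))),
      numeric(1))
    list(group = g, n = n, age_n = age_n, out_n = out_n,
         n_severe = sum(sel & severe))
  })
  names(rows) <- names(groups)

  reports_df <- data.frame(
    drug = names(groups),
    n = vapply(rows, `[[`, numeric(1), "n"),
    pct = percent_of(vapply(rows, `[[`, numeric(1), "n"), n_total),
    stringsAsFactors = FALSE, row.names = NULL)

  age_df <- do.call(rbind, lapply(rows, function(r)
    data.frame(drug = r$group, age_group = AGE_GROUPS, n = unname(r$age_n),
               pct = percent_of(unname(r$age_n), n_total),
               stringsAsFactors = FALSE)))
  rownames(age_df) <- NULL

  outcomes_df <- do.call(rbind, lapply(rows, function(r)
    data.frame(drug = r$group, outcome = OUTCOME_LEVELS[1:4],
               n = unname(r$out_n), pct = percent_of(unname(r$out_n), n_total),
               stringsAsFactors = FALSE)))
  rownames(outcomes_df) <- NULL

  severe_df <- data.frame(
    drug = names(groups),
    n_severe = vapply(rows, `[[`, numeric(1), "n_severe"),
    n = vapply(rows, `[[`, numeric(1), "n"),
    pct_of_total = percent_of(vapply(rows, `[[`, numeric(1), "n_severe"),
                              n_total),
    stringsAsFactors = FALSE, row.names = NULL)
  severe_df$pct_int <- ifelse(severe_df$n > 0,
                              round_half_up(100 * severe_df$n_severe /
                                              severe_df$n), 0)
  structure(list(n_total = n_total, reports = reports_df, age = age_df,
                 outcomes = outcomes_df, severe = severe_df),
            class = "pv_severity_summary")
}

#' @export
print.pv_severity_summary <- function(x, ...) {
  cat(sprintf("<pv_severity_summary> %d reports\n", x$n_total))
  print(x$reports, row.names = FALSE)
  invisible(x)
}

#' Distribution of signals over primary system organ classes
#'
#' Each signal row's PT rolls up to its single primary SOC; the returned
#' proportions are PT-signal counts per SOC over the total signal count, so
#' they sum to 1. Primary-only rollup (rather than multi-axial counting)
#' keeps the distribution a true partition.
#'
#' @param signal_rows Data frame with a `pt` column (e.g. flagged rows of
#'   [signal_table()] or [stratified_signal_table()]).
#' @param hierarchy A [pv_hierarchy]; every PT must resolve.
#' @return Data frame `soc`, `n`, `proportion`, sorted by count descending.
#' @export
soc_distribution <- function(signal_rows, hierarchy) {
  if (nrow(signal_rows) == 0L)
    stop("no signal rows to roll up", call. = FALSE)
  pts <- normalize_terms(signal_rows$pt)
  known <- unique(hierarchy$pt_to_socs$pt)
  orphans <- sort(unique(pts[!pts %in% known]))
  if (length(orphans))
    stop(sprintf("PT(s) not resolvable to a SOC: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  soc_of <- vapply(unique(pts), pt_to_soc, character(1),
                   hierarchy = hierarchy, mode = "primary_only")
  socs <- unname(soc_of[pts])
  tab <- sort(table(socs), decreasing = TRUE)
  data.frame(soc = names(tab), n = as.integer(tab),
             proportion = as.integer(tab) / length(socs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank signal rows by the interval lower bound
#'
#' Orders by ROR 95% lower bound descending (the conventional "relevant
#' intensity" ranking), breaking ties by co-report count descending, then PT
#' name ascending (then drug and age group, making the order total, so a
#' shuffled copy ranks identically) and keeps the top `k`.
#'
#' @param signal_rows Data frame with columns `ror_lo`, `a`, `pt` (and
#'   optionally `drug`, `age_group`).
#' @param k Maximum rows returned (default 50); `k <= 0` gives zero rows.
#' @return The top-`k` rows in rank order.
#' @export
rank_top_k <- function(signal_rows, k = 50) {
  if (k <= 0 || nrow(signal_rows) == 0L)
    return(signal_rows[0, , drop = FALSE])
  drug <- if ("drug" %in% names(signal_rows)) signal_rows$drug else ""
  agegr <- if ("age_group" %in% names(signal_rows)) signal_rows$age_group else ""
  ord <- order(-signal_rows$ror_lo, -signal_rows$a, signal_rows$pt,
               drug, agegr)
  out <- signal_rows[head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Age-stratified screened signal table
#'
#' For each (drug, age group) stratum the 2x2 tables are built within the
#' stratum — the comparator is the other drugs in the same stratum, so the
#' four cells partition the stratum — statistics are computed, and only
#' rows passing the overall screening flag are emitted. Strata with no
#' reports are skipped with a message.
#'
#' @param reports A deduplicated (and typically sex-filtered) [pv_reports]
#'   collection.
#' @param drugs Character vector of target drugs.
#' @param age_groups Age groups to scan (default: the four defined bins).
#' @param hierarchy Optional [pv_hierarchy]; when supplied a `soc_primary`
#'   column is added (PTs missing from the hierarchy get `NA`).
#' @param thresholds A [signal_thresholds()] object.
#' @return Data frame: `drug`, `age_group`, `pt`, `soc_primary` (optional),
#'   cells, statistics and flags; only `flag_overall` rows.
#' @export
stratified_signal_table <- function(reports, drugs,
                                    age_groups = AGE_GROUPS[1:4],
                                    hierarchy = NULL,
                                    thresholds = signal_thresholds()) {
  drugs <- normalize_terms(drugs)
  out <- list()
  for (ag in age_groups) {
    stratum <- reports[reports$age_group == ag, , drop = FALSE]
    if (nrow(stratum) == 0L) {
      message(sprintf("stratum %s is empty; skipped", ag))
      next
    }
    st <- signal_table(new_reports(stratum), drugs = drugs,
                       thresholds = thresholds, flagged_only = TRUE)
    if (nrow(st) == 0L) next
    st <- cbind(data.frame(age_group = ag, stringsAsFactors = FALSE), st)
    out[[ag]] <- st
  }
  if (!length(out)) {
    res <- cbind(data.frame(age_group = character(), drug = character(),
                            pt = character()),
                 disprop_stats(numeric(), numeric(), numeric(), numeric()))
    res <- apply_flags(res, thresholds)
  } else {
    res <- do.call(rbind, out)
  }
  res <- res[, c("drug", "age_group",
                 setdiff(names(res), c("drug", "age_group")))]
  if (!is.null(hierarchy) && nrow(res)) {
    known <- unique(hierarchy$pt_to_socs$pt)
    res$soc_primary <- vapply(res$pt, function(p)
      if (p %in% known) pt_to_soc(p, hierarchy) else NA_character_,
      character(1))
  }
  rownames(res) <- NULL
  res
}
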