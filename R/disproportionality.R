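#' @title Disproportionality statistics on 2x2 report tables
#' @description
#' For one drug--event pair within a filtered, deduplicated report set, the
#' 2x2 table counts reports with the drug and the event (`a`), the drug only
#' (`b`), the event only (`c`), and neither (`d`). The comparator is
#' "all other drugs in the set" (drug versus rest). On this table the
#' package computes the reporting odds ratio (ROR), proportional reporting
#' ratio (PRR), Pearson chi-square (Yates-corrected by default) and the
#' BCPNN information component (IC) with its closed-form posterior
#' approximation.
#' @name disproportionality
NULL

#' Construct a 2x2 contingency table from counts
#'
#' @param a,b,c,d Non-negative cell counts: drug+event, drug only, event
#'   only, neither.
#' @return An object of class `pv_table` with elements `a`,`b`,`c`,`d`,`N`.
#' @export
as_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d),
            class = "pv_table")
}

#' @export
print.pv_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "no drug"), c("event", "no event")))
  print(m)
  invisible(x)
}

#' Build the 2x2 table for a drug--event pair
#'
#' Membership is set containment on each report's normalized drug and event
#' sets, so a term listed twice in one case still counts once, and each
#' report contributes to exactly one cell.
#'
#' @param reports A deduplicated, filtered [pv_reports] collection.
#' @param drug,event Target generic drug name and event PT (normalized
#'   internally).
#' @return A `pv_table` (see [as_table()]).
#' @export
build_contingency <- function(reports, drug, event) {
  if (nrow(reports) == 0L)
    stop("empty report collection: no denominator for a contingency table",
         call. = FALSE)
  drug <- normalize_terms(drug)
  event <- normalize_terms(event)
  has_d <- vapply(reports$drugs, function(v) drug %in% v, logical(1))
  has_e <- vapply(reports$events, function(v) event %in% v, logical(1))
  as_table(sum(has_d & has_e), sum(has_d & !has_e),
           sum(!has_d & has_e), sum(!has_d & !has_e))
}

# Vectorized statistic core. All public scalar functions wrap this; the
# all-pairs signal table calls it directly on cell vectors.
disprop_stats <- function(a, b, c, d, z = 1.96) {
  corrected <- (a == 0 | b == 0 | c == 0 | d == 0)
  # Haldane-Anscombe: +0.5 on all four cells only when some cell is zero
  a2 <- a + 0.5 * corrected; b2 <- b + 0.5 * corrected
  c2 <- c + 0.5 * corrected; d2 <- d + 0.5 * corrected

  ror <- (a2 * d2) / (b2 * c2)
  se_ror <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  prr <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
  se_prr <- sqrt(pmax(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2), 0))

  ic <- ic_cells(a, b, c, d)
  data.frame(a = a, b = b, c = c, d = d,
             ror = ror,
             ror_lo = exp(log(ror) - z * se_ror),
             ror_hi = exp(log(ror) + z * se_ror),
             prr = prr,
             prr_lo = exp(log(prr) - z * se_prr),
             prr_hi = exp(log(prr) + z * se_prr),
             chi2 = chi2_cells(a, b, c, d, yates = TRUE),
             chi2_uncorrected = chi2_cells(a, b, c, d, yates = FALSE),
             ic = ic$ic,
             ic025 = ic$ic_minus_2sd,
             corrected = corrected)
}

chi2_cells <- function(a, b, c, d, yates = TRUE) {
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  zero_margin <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  Nv <- ifelse(N == 0, 1, N)
  e_a <- r1 * c1 / Nv; e_b <- r1 * c2 / Nv
  e_c <- r2 * c1 / Nv; e_d <- r2 * c2 / Nv
  dev <- abs(a - e_a)                      # equal for all 4 cells in a 2x2
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- dev^2 * (1 / e_a + 1 / e_b + 1 / e_c + 1 / e_d)
  chi2[zero_margin] <- 0
  if (any(zero_margin))
    warning("chi-square undefined for table(s) with a zero margin; returning 0")
  chi2
}

ic_cells <- function(a, b, c, d) {
  # Closed-form BCPNN information component (Bate et al. 1998 priors):
  # alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1, and gamma scaled so
  # that IC = 0 exactly when observed co-reporting equals expected.
  N <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  gamma <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  ic <- log2((a + g11) * (N + al) * (N + be) /
               ((N + gamma) * (a + b + a1) * (a + c + b1)))
  v <- (1 / log(2))^2 *
    ((N - a + gamma - g11) / ((a + g11) * (1 + N + gamma)) +
       (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
       (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be)))
  list(ic = ic, ic_minus_2sd = ic - 2 * sqrt(v))
}

wrap_estimate <- function(point, lower, upper, corrected) {
  structure(list(point = point, ci_lower = lower, ci_upper = upper,
                 corrected = corrected), class = "pv_estimate")
}

#' @export
print.pv_estimate <- function(x, ...) {
  cat(sprintf("%.2f (%.2f, %.2f)%s\n", x$point, x$ci_lower, x$ci_upper,
              if (x$corrected) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Reporting odds ratio with 95% Wald interval
#'
#' ROR = (a d)/(b c); 95% CI = exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d)).
#' If any cell is zero, 0.5 is added to all four cells first
#' (Haldane--Anscombe) and `corrected` is set. Because the interval is
#' log-symmetric, the point estimate equals the geometric mean of the
#' bounds.
#'
#' @param table A `pv_table`.
#' @return A `pv_estimate`: `point`, `ci_lower`, `ci_upper`, `corrected`.
#' @export
compute_ror <- function(table) {
  s <- disprop_stats(table$a, table$b, table$c, table$d)
  wrap_estimate(s$ror, s$ror_lo, s$ror_hi, s$corrected)
}

#' Proportional reporting ratio with 95% Wald interval
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\];
#' 95% CI = exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))).
#' Shares the continuity-correction rule of [compute_ror()].
#'
#' @param table A `pv_table`.
#' @return A `pv_estimate`.
#' @export
compute_prr <- function(table) {
  s <- disprop_stats(table$a, table$b, table$c, table$d)
  wrap_estimate(s$prr, s$prr_lo, s$prr_hi, s$corrected)
}

#' Pearson chi-square for the 2x2 table
#'
#' Expected counts come from the margins; with `yates = TRUE` (the classical
#' companion of the PRR criterion) 0.5 is subtracted from |O - E| (floored
#' at 0) before squaring. A zero margin yields 0 with a warning.
#'
#' @param table A `pv_table`.
#' @param yates Apply the Yates continuity correction (default `TRUE`).
#' @return Non-negative chi-square value.
#' @export
chi_square <- function(table, yates = TRUE) {
  unname(chi2_cells(table$a, table$b, table$c, table$d, yates = yates))
}

#' BCPNN information component
#'
#' Closed-form posterior-mean IC of the Bayesian Confidence Propagation
#' Neural Network, log2 of the shrunk observed-to-expected co-reporting
#' ratio, with the first-order variance expansion of the original method.
#' `ic_minus_2sd` (often written IC025) below 0 is the classical
#' no-signal region.
#'
#' @param table A `pv_table`.
#' @return List with `ic` and `ic_minus_2sd`.
#' @export
bcpnn_ic <- function(table) {
  ic_cells(table$a, table$b, table$c, table$d)
}

#' Screening thresholds for signal flags
#'
#' Literature-default criteria: ROR flag requires `a >= min_a` and a lower
#' 95% bound strictly above `ror_ci_lower_gt`; PRR flag requires
#' `prr >= prr_min`, `chi2 >= chi2_min` (Yates) and `a >= min_a`; BCPNN flag
#' requires `ic - 2sd > ic025_gt`. `combine` controls how the three method
#' flags merge into the overall flag (`"all"` = conjunction, `"any"`).
#'
#' @param min_a Minimum co-report count (default 3).
#' @param ror_ci_lower_gt ROR lower-bound threshold, strict (default 1).
#' @param prr_min PRR point threshold (default 2).
#' @param chi2_min Chi-square threshold (default 4).
#' @param ic025_gt IC - 2SD threshold, strict (default 0).
#' @param combine `"all"` or `"any"` (default `"all"`).
#' @return A `pv_thresholds` list.
#' @export
signal_thresholds <- function(min_a = 3, ror_ci_lower_gt = 1, prr_min = 2,
                              chi2_min = 4, ic025_gt = 0,
                              combine = c("all", "any")) {
  combine <- match.arg(combine)
  structure(list(min_a = min_a, ror_ci_lower_gt = ror_ci_lower_gt,
                 prr_min = prr_min, chi2_min = chi2_min, ic025_gt = ic025_gt,
                 combine = combine), class = "pv_thresholds")
}

apply_flags <- function(stats, thresholds) {
  t <- thresholds
  stats$flag_ror <- stats$a >= t$min_a & stats$ror_lo > t$ror_ci_lower_gt
  stats$flag_prr <- stats$prr >= t$prr_min & stats$chi2 >= t$chi2_min &
    stats$a >= t$min_a
  stats$flag_bcpnn <- stats$ic025 > t$ic025_gt
  stats$flag_overall <- if (t$combine == "all")
    stats$flag_ror & stats$flag_prr & stats$flag_bcpnn
  else
    stats$flag_ror | stats$flag_prr | stats$flag_bcpnn
  stats
}

#' Set per-method and overall signal flags
#'
#' Applies a [signal_thresholds()] object to a metrics data frame holding at
#' least columns `a`, `ror_lo`, `prr`, `chi2`, `ic025`, adding or replacing
#' `flag_ror`, `flag_prr`, `flag_bcpnn`, `flag_overall` (the conjunction of
#' the three methods by default — all three methods act as screening
#' conditions).
#'
#' @param metrics Data frame of computed statistics (e.g. from
#'   [signal_metrics()] or [signal_table()]).
#' @param thresholds A `pv_thresholds` object.
#' @return `metrics` with flag columns set.
#' @export
evaluate_signal <- function(metrics, thresholds = signal_thresholds()) {
  stopifnot(inherits(thresholds, "pv_thresholds"))
  apply_flags(metrics, thresholds)
}

#' All statistics and flags for one 2x2 table
#'
#' @param table A `pv_table`.
#' @param thresholds A [signal_thresholds()] object.
#' @return One-row data frame: cells, ROR/PRR with bounds, chi-square
#'   (Yates and uncorrected), IC, IC - 2SD, `corrected`, and the four flags.
#' @export
signal_metrics <- function(table, thresholds = signal_thresholds()) {
  apply_flags(disprop_stats(table$a, table$b, table$c, table$d), thresholds)
}

#' Screened signal table over all drug--event pairs
#'
#' Builds every 2x2 table within the supplied (deduplicated, filtered)
#' report set using report-level incidence, computes all statistics, and
#' applies the screening thresholds. The comparator for each drug is all
#' other drugs in the set.
#'
#' @param reports A deduplicated [pv_reports] collection.
#' @param drugs Optional character vector restricting the drugs scanned
#'   (default: every drug observed).
#' @param events Optional character vector restricting the event PTs
#'   (default: every event observed).
#' @param thresholds A [signal_thresholds()] object.
#' @param flagged_only Keep only rows with `flag_overall` (default `FALSE`).
#' @return Data frame with `drug`, `pt`, cells, statistics and flags, one
#'   row per pair with `a > 0`.
#' @export
signal_table <- function(reports, drugs = NULL, events = NULL,
                         thresholds = signal_thresholds(),
                         flagged_only = FALSE) {
  if (nrow(reports) == 0L)
    stop("empty report collection: no denominator for a contingency table",
         call. = FALSE)
  all_drugs <- sort(unique(unlist(reports$drugs)))
  all_events <- sort(unique(unlist(reports$events)))
  drugs <- if (is.null(drugs)) all_drugs else
    intersect(normalize_terms(drugs), all_drugs)
  events <- if (is.null(events)) all_events else
    intersect(normalize_terms(events), all_events)
  if (!length(drugs) || !length(events))
    return(cbind(data.frame(drug = character(), pt = character()),
                 apply_flags(disprop_stats(numeric(), numeric(), numeric(),
                                           numeric()), thresholds)))
  n <- nrow(reports)
  D <- vapply(drugs, function(dg)
    vapply(reports$drugs, function(v) dg %in% v, logical(1)),
    logical(n))
  E <- vapply(events, function(ev)
    vapply(reports$events, function(v) ev %in% v, logical(1)),
    logical(n))
  D <- matrix(D, nrow = n); E <- matrix(E, nrow = n)
  A <- crossprod(D, E)                     # co-report counts
  drug_n <- colSums(D); event_n <- colSums(E)
  pairs <- which(A >= 0, arr.ind = TRUE)   # all pairs
  a <- A[pairs]
  b <- drug_n[pairs[, 1]] - a
  c <- event_n[pairs[, 2]] - a
  d <- n - a - b - c
  out <- cbind(data.frame(drug = drugs[pairs[, 1]], pt = events[pairs[, 2]],
                          stringsAsFactors = FALSE),
               apply_flags(disprop_stats(a, b, c, d), thresholds))
  out <- out[out$a > 0, , drop = FALSE]
  if (flagged_only) out <- out[out$flag_overall, , drop = FALSE]
  out <- out[order(out$drug, out$pt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
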