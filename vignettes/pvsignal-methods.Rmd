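---
title: "Methods: disproportionality signal detection in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## Scope and model

Spontaneous reporting systems such as FAERS accumulate voluntary case
reports of suspected adverse drug events. Because there is no denominator
of exposed patients, association is assessed by *disproportionality*: is
event E reported more often with drug D than the rest of the database
would predict? `pvsignal` implements the three classical screening methods
on the 2×2 report table (a, b, c, d; N = a+b+c+d) built for each
drug–event pair:

* **ROR** = (a·d)/(b·c), 95% Wald CI
  exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)).
* **PRR** = [a/(a+b)]/[c/(c+d)], 95% Wald CI
  exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d))), with the Pearson
  χ² (Yates-corrected) as companion statistic.
* **BCPNN IC**: the closed-form information component
  IC = log₂[(a+γ₁₁)(N+α)(N+β) / ((N+γ)(a+b+α₁)(a+c+β₁))] with priors
  α₁ = β₁ = 1, α = β = 2, γ₁₁ = 1 and
  γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁)), and the first-order variance
  expansion of the original method; the Monte-Carlo posterior variant is
  deliberately out of scope. With these priors a balanced independent
  table gives IC = 0 exactly, and in large tables IC approaches the
  relative reporting ratio log₂[a·N/((a+b)(a+c))].

A pair is a positive signal when **all three** methods pass (the methods
act as joint screening conditions): a ≥ 3 with ROR lower bound > 1
(strict); PRR ≥ 2 with χ² ≥ 4 and a ≥ 3; IC − 2SD > 0 (strict). Every
threshold, and the conjunction-versus-disjunction rule, is overridable via
`signal_thresholds()`. The defaults are the literature-standard criteria;
a disjunctive or majority rule can be explored through the `combine`
argument. No multiple-testing correction is applied — conventional for
this screening setting, where flags are hypotheses, not confirmations.

**Comparator.** The denominator for each drug is *all other drugs in the
filtered report set* (drug versus rest). In the stratified table the
comparator is the other drugs *within the same age stratum*: that is the
only construction in which the four cells partition the stratum, making
per-stratum estimates self-contained. Whether published per-age estimates
were computed within-stratum or globally is generally ambiguous; the
within-stratum interpretation is implemented and stated here as an
assumption.

**Continuity correction.** When any cell is zero, 0.5 is added to all four
cells (Haldane–Anscombe) and the output is flagged `corrected`; tables
with all cells positive are never corrected, keeping ordinary estimates
identical to the uncorrected textbook formulas. The Wald intervals are
log-symmetric, so `point = sqrt(lower × upper)` holds to numerical
precision — a useful integrity check for any printed (ROR, CI) triple.

## Report model and normalization

The counting unit is the **deduplicated case**: per `case_id` only the
highest version is kept (ties broken by later file position), and within a
case each drug or PT counts once, preventing within-report double
counting. Drug, event and leaflet names all pass through one normalization
(uppercase, collapse whitespace, strip edge punctuation) so joins are
consistent everywhere.

Ages arrive in mixed units: years pass through, months divide by 12, days
by 365.25; unknown units or unparseable values become missing. Values
below 0 or above 120 years are treated as abnormal and merged with
missing, since reporting forms routinely contain impossible ages.
Fractional ages floor to whole years before binning into 0–18, 19–39,
40–59, ≥ 60, so the integer bin edges are honored exactly. Percentages in
the descriptive summary are rounded half-up at 2 decimals; per-drug severe
fractions additionally get the conventional integer-percent style.

## Hierarchy and keyword screening

The hierarchy model is LLT → PT → multi-axial SOC links with at most one
primary SOC per PT; the HLT/HLGT levels are omitted because no operation
here uses them. SOC distributions of signals use **primary-only** rollup
so the proportions form a true partition summing to 1; the `all` mode is
available for multi-axial sensitivity analysis. Keyword screening
(e.g. for developmental-toxicity terms) matches normalized keywords as
substrings of normalized LLT names — the simplest rule that is monotone in
the keyword list and needs no licensed dictionary resources. The packaged
~20-term keyword fixture is a synthetic stand-in exercising the mechanism;
real analyses should supply their full curated list.

## Synthetic generator and its ground truth

The generator draws, per case: sex and age group from configured mixtures
(with an in-bin age value, sometimes expressed in months for infants, and
an 80/20 missing/abnormal split inside the residual bucket); independent
Bernoulli drug indicators, resampled until nonempty; independent Bernoulli
event indicators whose **odds** are multiplied by λ for each planted
(drug, event) association whose drug is present and age restriction
matches, resampled until nonempty; independent outcome indicators; and,
with probability `duplicate_fraction`, an earlier duplicate case version.

Planting on the odds scale makes recovery tests sharp: conditioning on "at
least one event" multiplies the event odds by the same factor in the drug
and no-drug arms, so for a configuration with a single planted pair the
true report-level odds ratio equals λ *exactly*. `expected_table()`
computes exact expected cells under the full model — enumerating drug
subsets × age groups and applying both rejection conditionings — and is
the oracle for all recovery tests. With several simultaneous plants the
*marginal* odds ratio of a planted pair deviates slightly from λ
(odds-ratio non-collapsibility across the induced strata; e.g. 8.02 for
λ = 8 under the defaults), which `expected_table()` reflects; tests
therefore always target its value, not λ itself.

Defaults are fixed study conditions, not tuning knobs: the four imidazole
drugs carry marginal probabilities equal to the published report shares
(0.2259/0.0491/0.1904/0.5346), age-bin masses follow the published age
table (including a ~35% missing/abnormal bucket), outcome probabilities
sit near the published severity rates, sex is female-dominant
(0.90/0.07/0.03) but mixed so the female-restriction filter does real
work, and `duplicate_fraction = 0.1` reflects the well-known duplication
of spontaneous reports. A separate deterministic fixture,
`reference_reports()`, reconstructs the exact published marginal counts
(9985 reports) so the descriptive summary reproduces the printed
percentages digit-for-digit.

What the generator does **not** emulate: reporting trends over time,
drug–drug interactions, masking/competition bias, country effects, and
free-text drug-name noise. Passing recovery tests therefore demonstrates
correctness of the statistics and plumbing under a clean generative model,
not robustness to every artefact of real spontaneous data.

## Numerical and degenerate-input choices

* Zero cells: Haldane–Anscombe correction as above; zero χ² margins return
  0 with a warning rather than NaN.
* An empty report collection is an error for table construction (no
  denominator) but an empty *source file* parses to an empty collection.
* Ranking by ROR lower bound breaks ties by case count (descending), then
  PT, drug and age group (ascending), making the order total — a shuffled
  input ranks identically.
* Strata with no reports are skipped with a message; strata where a pair's
  `a` falls below `min_a` are suppressed by the count threshold itself.
* All generator randomness flows from the single config seed, and the
  session RNG state is restored afterwards.

## Problem sizes used in validation

The test suite validates the statistics against hand-computed and
brute-force oracles (all 1296 tables with cells 1–6 for the ROR/PRR
ordering; 100 datasets of n = 500 for the contingency oracle), checks CI
coverage of a planted λ = 10 association across 200 simulations of
n = 5000 reports, bounds the null flagged-pair rate across 20 simulations
of n = 2000, and checks empirical-versus-analytic cell convergence at
n = 100,000. These sizes give stable Monte-Carlo behavior while keeping
the full suite fast enough to run routinely.

## Known limitations

* Wald intervals are first-order approximations; for very sparse tables
  (a ≤ 2) the flags rely on the `min_a` floor rather than interval
  accuracy.
* The BCPNN variance is the closed-form expansion, slightly
  anti-conservative versus the Monte-Carlo posterior in tiny tables.
* Exact-count deduplication assumes consistent `case_id`s; probabilistic
  duplicate detection across different ids is out of scope.
* The packaged hierarchy and leaflet files are small synthetic fixtures
  for testing the mechanics, not clinical resources.
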