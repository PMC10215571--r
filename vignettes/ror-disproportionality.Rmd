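---
title: "Disproportionality screening of spontaneous ADR reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous ADR reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorscreen)
```

## The problem

Spontaneous-report databases such as EudraVigilance collect Individual Case
Safety Reports (ICSRs): one report per patient describing suspected drugs and
the observed adverse reactions, coded as MedDRA preferred terms (PTs).
Reports whose PTs indicate *drug resistance* (DR) or *drug ineffectiveness*
(DI) are of particular interest for antimicrobial-resistance surveillance: a
rising share of such reports for an antibiotic is an early warning that the
drug is failing in the field.

`rorscreen` implements the full analysis chain for this question:

1. a data model and line-list store for ICSRs,
2. PT query sets for the DR and DI categories,
3. stratified descriptive tables (age band, sex, origin, reporter group) and
   category summaries with fatal fractions,
4. pairwise disproportionality statistics (reporting odds ratio with Wald
   confidence interval) with a signal-of-disproportionate-reporting rule, and
5. a seeded synthetic ICSR generator providing ground truth for every stage.

## The category query sets

The DR category contains three PTs ("drug resistance", "multiple-drug
resistance", "pathogen resistance"); the DI category contains nine
("drug ineffective", "treatment failure", "therapeutic product ineffective",
and six further therapeutic-failure terms — see `builtin_categories()`).
PTs are flat strings here: no MedDRA hierarchy (SOC/HLT) navigation is
attempted, which keeps the package free of MedDRA licensing concerns.

Matching is case-insensitive and whitespace-normalized, because portals print
the same PT with varying capitalization. One PT circulates under two
spellings — "multiple-drug resistance" and "multi-drug resistance" — so the
latter is registered as an alias of the former; both count as the same
member. A case is *in* a category when its reaction set intersects the
member set; a case carrying two member PTs is still one case (set
semantics), although it increments both rows of the per-PT breakdown.

## Counting conventions

All descriptive and disproportionality counts are **case-level** (ICSRs),
not reaction-level. Portal figures label their counts as "reports", and the
reproducible published percentages (83/986, 170/316, ...) are consistent only
with case-level counting, so the package uses it uniformly — including in
the 2×2 contingency tables, where `a` is the number of target-drug *cases*
reporting at least one category PT.

The fatal fraction of a category is reported with the category's own case
count as denominator (fatal DR cases / DR cases). The alternative reading —
fatal category cases over *all* cases for the drug — cannot be
distinguished from published percentages alone; we adopt the within-category
reading because it is the quantity a clinician asks for ("how often is a
resistance report fatal?") and it is scale-free across drugs of very
different reporting volume.

Percentages are computed at full precision and rendered at two decimals,
rounded half-away-from-zero (`format_percent()`); published figures mix zero
to two printed decimals, so comparisons against them are made at their
printed precision.

## The disproportionality model

For a target drug and a comparator, with

* `a` = target cases in the category, `b` = target cases outside it,
* `c` = comparator cases in the category, `d` = comparator cases outside it,

the reporting odds ratio is `ROR = (a d) / (b c)`, the standard error of its
logarithm is `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, and the 95% CI is
`exp(ln ROR ± 1.96 SE)`. The multiplier is fixed at exactly 1.96 for the
conventional 0.05 level (matching how the interval is universally printed);
any other `alpha` uses the exact normal quantile. A case naming both drugs
as suspected contributes to both margins — spontaneous databases do not
de-duplicate co-suspect reports, and the generator can produce such cases to
exercise the rule.

A **signal of disproportionate reporting** requires *both* at least five
reports in the target cell (`a ≥ 5`, counted before any correction) *and* a
CI lower bound strictly above 1. A lower bound exactly at 1 does not signal.
This is the standard SDR convention for ROR screens of rare-event categories.

Design choices worth making explicit:

* **Zero cells.** Rare-event comparators produce zero cells. The default
  policy is the Haldane–Anscombe correction (+0.5 on all four cells, table
  flagged `corrected`) so that a screen over many comparators never aborts;
  a strict `"error"` policy is available for analyses that prefer to fail.
  `n_reports` always remains the uncorrected `a`.
* **p-values and stars.** Screens are conventionally annotated with
  significance stars. Sources for such screens rarely state their test; we
  compute a two-sided normal (Wald) test on the log ROR, the test whose SE
  the CI already uses, and isolate it in one place so a different test could
  be substituted. The star ladder is * p < 0.05, ** p ≤ 0.01, *** p ≤ 0.001,
  **** p ≤ 0.0001.
* **One pooled 2×2 per category.** Each drug pair gets one table per
  category (all member PTs pooled), not per-PT tables; screens of this kind
  present one ROR per pair per category.
* **Screen robustness.** A comparator absent from the dataset yields a row
  flagged `available = FALSE` with a warning, not an abort; the pipeline log
  records these events together with Haldane corrections and any
  `"Not specified"` coercions at read time, as the run's data-quality report.

## The synthetic generator

`generate_cases()` emulates a multi-drug spontaneous-report database. Per
drug profile: category memberships are independent Bernoulli draws with the
profile's per-category probabilities; a member PT is drawn by configurable
weights for each membership; one to three background (non-category) PTs are
always added, uniformly — multi-symptom reports are the norm in real data
and the exact count distribution is immaterial to any statistic the package
computes; demographics are categorical draws; the fatal flag is Bernoulli
with the category-conditional probability (maximum over the case's
categories, background rate otherwise — category overlap is rare under
independent membership, so the conditional fatality of each category is
preserved to well within sampling noise).

Randomness is forked per drug profile: each profile's stream is seeded by a
hash of the master seed and the drug token, so adding or reordering drugs
never perturbs another drug's cases — which keeps regression tests stable
and makes scenario edits reviewable.

`calibrated_scenario()` is the calibrated instance: colistin (986 ICSRs,
DR probability 0.0842, DI 0.1014), meropenem (8,864; 0.0356; 0.0945) and
linezolid (13,381; 0.0238; 0.0415), with sex/origin/reporter weights and
category-conditional fatality rates (DR: 0.24/0.20/0.06, DI: 0.35/0.28/0.19)
set to the published margins of the motivating portal snapshot, and per-PT
weights proportional to the published PT counts. Where only two age-band
shares are published per drug, the remaining mass is spread over the other
bands in small realistic proportions (fixed once in the source); origin
"Not specified" is set to zero (two reports in ~23,000 in the source data)
and reporter "Not specified" to 0.005 ("a few"). The linezolid DI case count
is never published — only the share 4.15% — so the scenario stores the
probability, and the PT-weight denominator uses 556 = round(372/0.6691),
the count implied by the published leading-PT share. Ten generic comparator
profiles (default 5,000 cases, DR 0.01, DI 0.04, configurable) complete the
thirteen-drug design.

What the generator does *not* model: reporting-time dynamics, duplicate
submissions, under-reporting, correlated DR/DI membership, and any
drug–demographic interaction. Tests passing on synthetic data therefore
validate the *computational chain* — counting, tables, estimator, rule —
under a known truth; they say nothing about reporting biases in real
spontaneous data, which remain the analyst's burden.

## Numerical and validation choices

* The ROR estimator is validated two ways: exact-fraction fixtures (e.g.
  `(4, 6, 2, 18)` → ROR exactly 6, `SE = sqrt(35/36)`), and an independent
  route — the Wald estimate and SE from a binomial `glm` on the aggregated
  2×2, which must agree to 1e-6.
* Property suites over 1,000 random tables check reciprocity
  (swapping the drugs inverts the ROR and mirrors the CI), strict
  monotonicity in `a`, and CI geometry (point estimate inside, log-width
  shrinking as cells scale).
* Parameter recovery: two arms of 20,000 cases with category probabilities
  0.10 vs 0.05 (true odds ratio 19/9 ≈ 2.111), 200 replicates: the mean
  estimate must sit within 2% of truth and the 95% CI must cover it in
  91–98% of replicates (binomial tolerance at 200 replicates). Under
  identical rates (0.05, 5,000 per arm, 400 replicates) the signal frequency
  must stay at or below 5% — the rule is one-sided, so ~2.5% is expected.
  These problem sizes make the whole validation suite run in about two
  minutes on a laptop core while leaving Monte-Carlo error well inside the
  asserted bands.
* Degenerate inputs: empty datasets produce zero-count tables with undefined
  (NA) percentages; a drug with no cases is an error for summaries (the
  percentage is undefined) and a flagged-unavailable row for screens;
  `compute_ror` refuses nonpositive cells rather than silently correcting.

## Limitations

The package reproduces published *percentages* exactly from their printed
counts, but published ROR values against named comparators are not
reproducible from any fixture: the comparator contingency cells were never
printed and the source database is live. The screen is therefore validated
by construction (known-truth simulation) rather than by value matching.
PRR, IC/BCPNN and EBGM statistics are out of scope; the screen's column
layout leaves room for them, and `compute_ror()`'s interface (cells in,
result object out) is the template an extension would follow.
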