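# rorscreen

Disproportionality screening of spontaneous adverse-drug-reaction reports,
aimed at antimicrobial-resistance surveillance.

Pharmacovigilance databases (EudraVigilance, FAERS, VigiBase) collect
Individual Case Safety Reports (ICSRs): one report per patient, listing
suspected drugs and adverse reactions coded as MedDRA preferred terms (PTs).
For an antibiotic, a disproportionate share of reports whose PTs indicate
**drug resistance** (DR — 3 PTs: "drug resistance", "multiple-drug
resistance", "pathogen resistance") or **drug ineffectiveness** (DI — 9 PTs,
e.g. "drug ineffective", "treatment failure") is an early warning that the
drug is failing in the field. `rorscreen` is for pharmacoepidemiologists and
antimicrobial-stewardship analysts who want that screen as reproducible code
rather than a spreadsheet.

## What it computes

Given a line-list of ICSRs (case id, suspected drugs, reaction PTs, EMA age
band, sex, EEA/non-EEA origin, reporter group, fatal flag):

* **Descriptives** — per-drug distributions over the four stratifiers, and
  per-category summaries: case counts, percentages, fatal fractions, per-PT
  breakdowns (`distribution_by()`, `category_summary()`).
* **Disproportionality** — for each (target, comparator, category) triple
  the 2×2 table *a, b, c, d* of category vs non-category cases, and the
  reporting odds ratio

  ROR = (a·d)/(b·c),  SE{ln ROR} = √(1/a + 1/b + 1/c + 1/d),
  95% CI = exp(ln ROR ± 1.96·SE)

  with a two-sided Wald p-value and significance stars
  (`build_contingency()`, `compute_ror()`, `screen()`). Zero cells take the
  Haldane–Anscombe +0.5 correction by default.
* **Signal rule** — a signal of disproportionate reporting (SDR) requires at
  least 5 reports in the target cell **and** a CI lower bound above 1
  (`detect_signal()`).
* **Synthetic ground truth** — a seeded generator of multi-drug report
  databases with known category probabilities, demographics and fatality
  rates (`generate_cases()`, `calibrated_scenario()`), so estimator bias,
  CI coverage and the false-signal rate are all testable
  (`ror_recovery_sim()`, `null_signal_sim()`).
* **Pipeline** — `run_pipeline()` goes from a line-list (or a scenario) to
  delimited tables, a data-quality log and a manifest in one call.

## Worked example

The `analysis/` scripts run the whole study on a simulated database:

```sh
Rscript analysis/01_simulate.R        # 13-drug synthetic database
Rscript analysis/02_descriptives.R    # stratified tables + category summaries
Rscript analysis/03_screen.R          # 60-row ROR screen
Rscript analysis/04_operating_characteristics.R
```

`01_simulate.R` generates 73,231 ICSRs: three calibrated target antibiotics
— colistin (COL, 986 cases), meropenem (MER, 8,864), linezolid (LIN, 13,381)
— and ten generic comparator antimicrobials. `02_descriptives.R` then
prints, for example:

```
COL: 986 ICSRs
  age_group  dominated by 18-64 years                 47.67%
  sex        dominated by Male                        52.13%
  origin     dominated by EEA                         74.95%
  reporter   dominated by Healthcare professional     90.06%
  DR: 83/986 cases (8.42%), fatal 26.51%
  DI: 105/986 cases (10.65%), fatal 33.33%
```

i.e. 8.42% of colistin reports flag drug resistance, of which 26.51% had a
fatal outcome — each number an empirical draw around the scenario's
configured rates (DR probability 0.0842, fatal-given-DR 0.24).
`03_screen.R` reports each signal with its ROR and CI:

```
screened 60 triples (3 targets x 10 comparators x 2 categories)
signals of disproportionate reporting: 50
  COL  vs MOX      DR  ROR   8.4188 (95% CI  5.9330- 11.9461) ****
  ...
```

a COL-vs-moxifloxacin DR reporting odds ratio of 8.4 whose CI excludes 1
with ≥ 5 reports — a signal. `04_operating_characteristics.R` validates the
engine against ground truth:

```
  true OR 2.1111 | mean estimate 2.1136 | CI coverage 95.0%
  false-signal frequency 3.50% (rule is one-sided, nominal <= 2.5%)
```

The same steps are available programmatically:

```r
library(rorscreen)
scenario <- calibrated_scenario(seed = 42)
config <- run_config(
  target_drugs = c("COL", "MER", "LIN"),
  comparator_drugs = c("MOX", "TIG", "PIP/TAZ", "CEF/AVI", "VAN",
                       "FLU", "ISA", "CAP", "AMF", "VOR"),
  seed = 42
)
art <- run_pipeline("synthetic", config, "out", scenario = scenario)
head(art$screen)
```

See `vignettes/ror-disproportionality.Rmd` for the model, the counting
conventions, every tunable parameter, and what synthetic validation does and
does not demonstrate.

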