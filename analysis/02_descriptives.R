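#!/usr/bin/env Rscript
# Stratified descriptive analysis of the simulated database: per target drug,
# the distribution of ICSRs over age band, sex, geographic origin and
# reporter group, plus the drug-resistance / drug-ineffectiveness category
# summaries with fatal fractions and per-PT breakdowns.
# Reads results/linelist.csv (from 01_simulate.R); writes tables under
# results/descriptives/.

suppressMessages(library(rorscreen))

cases <- read_linelist("results/linelist.csv")
config <- read_run_config("results/run_config.yml")
dir.create("results/descriptives", showWarnings = FALSE, recursive = TRUE)

for (drug in config$target_drugs) {
  drug_cases <- cases_for_drug(cases, drug)
  cat(sprintf("\n%s: %d ICSRs\n", drug, nrow(drug_cases)))
  for (v in c("age_group", "sex", "origin", "reporter")) {
    tab <- distribution_by(drug_cases, v)
    readr::write_csv(tab, sprintf("results/descriptives/%s_%s.csv",
                                  gsub("[^A-Za-z0-9]+", "_", drug), v))
    top <- tab[which.max(tab$count), ]
    cat(sprintf("  %-10s dominated by %-26s %6.2f%%\n",
                v, top$stratum, top$percent))
  }
  for (cat_obj in config$categories) {
    cs <- category_summary(cases, drug, cat_obj)
    readr::write_csv(cs$pt_breakdown,
                     sprintf("results/descriptives/%s_%s_pts.csv",
                             gsub("[^A-Za-z0-9]+", "_", drug), cs$category))
    cat(sprintf("  %s: %d/%d cases (%s%%), fatal %s%%\n",
                cs$category, cs$n_cases, cs$n_total,
                format_percent(cs$n_cases, cs$n_total),
                if (is.na(cs$fatal_percent)) "-" else
                  format_percent(cs$fatal_n, cs$n_cases)))
  }
}
cat("\nwrote per-drug tables under results/descriptives/\n")
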