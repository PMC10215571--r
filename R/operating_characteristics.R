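oc_two_arm_scenario <- function(n_per_arm, p_target, p_comparator, seed) {
  dr <- builtin_categories()["DR"]
  members <- dr$DR$members
  mk <- function(drug, p) drug_profile(
    drug = drug, n_cases = as.integer(n_per_arm),
    p_category = c(DR = p),
    pt_weights = list(DR = stats::setNames(rep(1, length(members)), members)),
    p_fatal_given_category = c(DR = 0.2),
    p_fatal_background = 0.05,
    demographics = list(
      age_group = c("18-64 years" = 1), sex = c("Male" = 1),
      origin = c("EEA" = 1), reporter = c("Healthcare professional" = 1)
    )
  )
  scenario_config(list(mk("TARGET", p_target), mk("COMPARATOR", p_comparator)),
                  categories = dr, seed = seed)
}

#' Monte-Carlo operating characteristics of the ROR screen
#'
#' `ror_recovery_sim()` repeatedly generates a two-arm synthetic database in
#' which the target drug reports the category with probability `p_target`
#' and the comparator with `p_comparator` — so the true reporting odds ratio
#' is `(p_target/(1-p_target)) / (p_comparator/(1-p_comparator))` — and runs
#' the full pipeline path (generator, contingency, ROR, CI, signal rule) on
#' each replicate. `null_signal_sim()` is the special case
#' `p_target == p_comparator`, whose signal frequency estimates the rule's
#' false-signal rate.
#'
#' @param n_per_arm ICSRs generated per drug per replicate.
#' @param p_target,p_comparator Per-case category reporting probabilities.
#' @param replicates Number of Monte-Carlo replicates.
#' @param seed Master seed; replicate r uses sub-seed `seed + r`.
#' @return A tibble with one row per replicate: `ror`, `ci_low`, `ci_high`,
#'   `signal`, `covered` (CI covers the true odds ratio), plus the true
#'   `true_or` as an attribute.
#' @export
ror_recovery_sim <- function(n_per_arm, p_target, p_comparator,
                             replicates, seed = 1L) {
  true_or <- (p_target / (1 - p_target)) / (p_comparator / (1 - p_comparator))
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sc <- oc_two_arm_scenario(n_per_arm, p_target, p_comparator,
                              seed = as.integer(seed) + r)
    cases <- generate_cases(sc)
    tab <- build_contingency(cases, "TARGET", "COMPARATOR",
                             builtin_categories()$DR)
    res <- compute_ror(tab)
    rows[[r]] <- tibble::tibble(
      ror = res$ror, ci_low = res$ci_low, ci_high = res$ci_high,
      signal = res$signal,
      covered = res$ci_low <= true_or && true_or <= res$ci_high
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "true_or") <- true_or
  out
}

#' @rdname ror_recovery_sim
#' @param p_common Shared category probability of both arms under the null.
#' @export
null_signal_sim <- function(n_per_arm, p_common, replicates, seed = 1L) {
  ror_recovery_sim(n_per_arm, p_common, p_common, replicates, seed = seed)
}
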