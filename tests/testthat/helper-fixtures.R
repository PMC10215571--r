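# Small in-code fixtures shared across test files.

# A hand-enumerable mixed dataset: `n_target` cases for `target` of which
# `k_target` carry a DR member PT, likewise for the comparator.
two_arm_fixture <- function(target = "drugA", comparator = "drugB",
                            n_target = 10, k_target = 4,
                            n_comparator = 20, k_comparator = 2) {
  n <- n_target + n_comparator
  drugs <- c(rep(target, n_target), rep(comparator, n_comparator))
  reactions <- vector("list", n)
  in_cat <- c(seq_len(k_target),
              n_target + seq_len(k_comparator))
  for (i in seq_len(n)) {
    reactions[[i]] <- if (i %in% in_cat) c("Drug resistance", "Nausea") else "Nausea"
  }
  icsr_dataset(
    case_id = sprintf("c%03d", seq_len(n)),
    drugs = as.list(drugs),
    reactions = reactions,
    age_group = rep("18-64 years", n),
    sex = rep(c("Male", "Female"), length.out = n),
    origin = rep("EEA", n),
    reporter = rep("Healthcare professional", n),
    fatal = rep(FALSE, n)
  )
}

# Deterministic dataset realizing exact printed counts: `n` cases for `drug`,
# the first `k_dr` in DR, the next `k_di` in DI (disjoint blocks).
counted_fixture <- function(drug, n, k_dr, k_di,
                            dr_pt = "drug resistance",
                            di_pt = "drug ineffective") {
  reactions <- rep(list("Nausea"), n)
  if (k_dr > 0) reactions[seq_len(k_dr)] <- list(c(dr_pt, "Nausea"))
  if (k_di > 0) reactions[k_dr + seq_len(k_di)] <- list(c(di_pt, "Nausea"))
  icsr_dataset(
    case_id = sprintf("%s-%05d", drug, seq_len(n)),
    drugs = as.list(rep(drug, n)),
    reactions = reactions,
    age_group = rep("18-64 years", n),
    sex = rep("Male", n),
    origin = rep("EEA", n),
    reporter = rep("Healthcare professional", n),
    fatal = rep(FALSE, n)
  )
}

# Random small dataset for property tests, built with base R only (no use of
# the package generator) so it is an independent input source.
random_small_dataset <- function(seed, n_max = 40) {
  set.seed(seed)
  n <- sample(1:n_max, 1)
  all_pts <- c("Drug resistance", "Pathogen resistance", "Drug ineffective",
               "Treatment failure", "Nausea", "Rash", "Headache", "Pyrexia")
  drugs_pool <- c("alpha", "beta", "gamma")
  icsr_dataset(
    case_id = sprintf("r%04d", seq_len(n)),
    drugs = lapply(seq_len(n), function(i)
      sample(drugs_pool, sample(1:2, 1))),
    reactions = lapply(seq_len(n), function(i)
      sample(all_pts, sample(1:4, 1))),
    age_group = sample(icsr_age_groups(), n, replace = TRUE),
    sex = sample(icsr_sexes(), n, replace = TRUE),
    origin = sample(icsr_origins(), n, replace = TRUE),
    reporter = sample(icsr_reporters(), n, replace = TRUE),
    fatal = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
}

# Minimal single-category profile for operating-characteristic simulations.
bernoulli_profile <- function(drug, n, p_dr, category = builtin_categories()$DR) {
  drug_profile(
    drug = drug, n_cases = as.integer(n),
    p_category = c(DR = p_dr),
    pt_weights = list(DR = stats::setNames(rep(1, length(category$members)),
                                           category$members)),
    p_fatal_given_category = c(DR = 0.2),
    p_fatal_background = 0.05,
    demographics = list(
      age_group = c("18-64 years" = 1), sex = c("Male" = 1),
      origin = c("EEA" = 1), reporter = c("Healthcare professional" = 1)
    )
  )
}
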