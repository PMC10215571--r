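#' Calibrated antimicrobial surveillance scenario
#'
#' A 13-drug scenario emulating the public-portal snapshot behind the
#' package's motivating analysis: three target antibiotics — colistin (COL,
#' 986 ICSRs), meropenem (MER, 8,864) and linezolid (LIN, 13,381) — with
#' drug-resistance and drug-ineffectiveness reporting probabilities,
#' demographic mixes, per-PT weights and category-conditional fatality rates
#' taken from the printed summary statistics of that snapshot, plus ten
#' generic comparator antimicrobials (MOX, TIG, PIP/TAZ, CEF/AVI, VAN, FLU,
#' ISA, CAP, AMF, VOR) with configurable size and rates.
#'
#' @param seed Master seed for the scenario.
#' @param comparator_n ICSR count per comparator drug (default 5000).
#' @param comparator_p_dr,comparator_p_di Category reporting probabilities
#'   for the comparators (defaults 0.01 and 0.04).
#' @return A [scenario_config()] with 13 profiles.
#' @export
calibrated_scenario <- function(seed = 1L, comparator_n = 5000L,
                                  comparator_p_dr = 0.01,
                                  comparator_p_di = 0.04) {
  cats <- builtin_categories()
  dr <- cats$DR$members
  di <- cats$DI$members

  # DI PT weights: the three dominant PTs at their published shares, the
  # remaining six members sharing the published residual equally
  di_weights <- function(top3, residual_each) {
    w <- stats::setNames(rep(residual_each, length(di)), di)
    w[names(top3)] <- top3
    w
  }

  demo <- function(age, sex, origin, reporter) {
    list(age_group = age, sex = sex, origin = origin, reporter = reporter)
  }

  col <- drug_profile(
    drug = "COL", n_cases = 986L,
    p_category = c(DR = 0.0842, DI = 0.1014),
    pt_weights = list(
      DR = c("drug resistance" = 46, "pathogen resistance" = 28,
             "multiple-drug resistance" = 9),
      DI = di_weights(c("drug ineffective" = 85, "treatment failure" = 5,
                        "drug ineffective for unapproved indication" = 4), 1)
    ),
    p_fatal_given_category = c(DR = 0.24, DI = 0.35),
    p_fatal_background = 0.05,
    demographics = demo(
      age = c("0-1 month" = 0.005, "2 months-2 years" = 0.02,
              "3-11 years" = 0.03, "12-17 years" = 0.02,
              "18-64 years" = 0.49, "65-85 years" = 0.28,
              ">85 years" = 0.03, "Not specified" = 0.125),
      sex = c(Female = 0.433, Male = 0.529, "Not specified" = 0.038),
      origin = c(EEA = 0.75, "Non-EEA" = 0.25),
      reporter = c("Healthcare professional" = 0.89,
                   "Non-healthcare professional" = 0.105,
                   "Not specified" = 0.005)
    )
  )

  mer <- drug_profile(
    drug = "MER", n_cases = 8864L,
    p_category = c(DR = 0.0356, DI = 0.0945),
    pt_weights = list(
      DR = c("drug resistance" = 170, "pathogen resistance" = 125,
             "multiple-drug resistance" = 21),
      DI = di_weights(c("drug ineffective" = 683, "treatment failure" = 54,
                        "drug ineffective for unapproved indication" = 35), 11)
    ),
    p_fatal_given_category = c(DR = 0.20, DI = 0.28),
    p_fatal_background = 0.05,
    demographics = demo(
      age = c("0-1 month" = 0.005, "2 months-2 years" = 0.025,
              "3-11 years" = 0.035, "12-17 years" = 0.02,
              "18-64 years" = 0.43, "65-85 years" = 0.32,
              ">85 years" = 0.04, "Not specified" = 0.125),
      sex = c(Female = 0.411, Male = 0.553, "Not specified" = 0.036),
      origin = c(EEA = 0.40, "Non-EEA" = 0.60),
      reporter = c("Healthcare professional" = 0.96,
                   "Non-healthcare professional" = 0.035,
                   "Not specified" = 0.005)
    )
  )

  lin <- drug_profile(
    drug = "LIN", n_cases = 13381L,
    p_category = c(DR = 0.0238, DI = 0.0415),
    pt_weights = list(
      DR = c("drug resistance" = 142, "pathogen resistance" = 165,
             "multiple-drug resistance" = 12),
      DI = di_weights(c("drug ineffective" = 372, "treatment failure" = 96,
                        "drug ineffective for unapproved indication" = 34), 9)
    ),
    p_fatal_given_category = c(DR = 0.06, DI = 0.19),
    p_fatal_background = 0.05,
    demographics = demo(
      age = c("0-1 month" = 0.005, "2 months-2 years" = 0.02,
              "3-11 years" = 0.03, "12-17 years" = 0.02,
              "18-64 years" = 0.41, "65-85 years" = 0.35,
              ">85 years" = 0.045, "Not specified" = 0.12),
      sex = c(Female = 0.388, Male = 0.544, "Not specified" = 0.068),
      origin = c(EEA = 0.38, "Non-EEA" = 0.62),
      reporter = c("Healthcare professional" = 0.89,
                   "Non-healthcare professional" = 0.105,
                   "Not specified" = 0.005)
    )
  )

  comparator_names <- c("MOX", "TIG", "PIP/TAZ", "CEF/AVI", "VAN",
                        "FLU", "ISA", "CAP", "AMF", "VOR")
  comparators <- lapply(comparator_names, function(nm) {
    drug_profile(
      drug = nm, n_cases = as.integer(comparator_n),
      p_category = c(DR = comparator_p_dr, DI = comparator_p_di),
      pt_weights = list(
        DR = stats::setNames(rep(1, length(dr)), dr),
        DI = stats::setNames(rep(1, length(di)), di)
      ),
      p_fatal_given_category = c(DR = 0.15, DI = 0.15),
      p_fatal_background = 0.05,
      demographics = demo(
        age = c("18-64 years" = 0.5, "65-85 years" = 0.3,
                "3-11 years" = 0.05, ">85 years" = 0.05,
                "Not specified" = 0.1),
        sex = c(Female = 0.45, Male = 0.5, "Not specified" = 0.05),
        origin = c(EEA = 0.5, "Non-EEA" = 0.5),
        reporter = c("Healthcare professional" = 0.9,
                     "Non-healthcare professional" = 0.095,
                     "Not specified" = 0.005)
      )
    )
  })

  scenario_config(
    profiles = c(list(col, mer, lin), comparators),
    categories = cats,
    seed = seed
  )
}

#' Read and write scenario configurations
#'
#' YAML serialization of a [scenario_config()], in the same config format as
#' [run_config()] files.
#'
#' @param scenario A `scenario_config`.
#' @param path Config file path.
#' @return `read_scenario_config()` returns a `scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  yaml::write_yaml(list(
    seed = scenario$seed,
    background_vocab = as.list(scenario$background_vocab),
    categories = lapply(scenario$categories, `[[`, "members"),
    profiles = lapply(scenario$profiles, function(p) {
      list(
        drug = p$drug, n_cases = p$n_cases,
        p_category = as.list(p$p_category),
        pt_weights = lapply(p$pt_weights, as.list),
        p_fatal_given_category = as.list(p$p_fatal_given_category),
        p_fatal_background = p$p_fatal_background,
        demographics = lapply(p$demographics, as.list),
        co_suspect = p$co_suspect, co_suspect_rate = p$co_suspect_rate
      )
    })
  ), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  cats <- lapply(names(y$categories),
                 function(nm) adr_category(nm, unlist(y$categories[[nm]])))
  profiles <- lapply(y$profiles, function(p) {
    drug_profile(
      drug = p$drug, n_cases = p$n_cases,
      p_category = unlist(p$p_category),
      pt_weights = lapply(p$pt_weights, unlist),
      p_fatal_given_category = unlist(p$p_fatal_given_category),
      p_fatal_background = p$p_fatal_background,
      demographics = lapply(p$demographics, unlist),
      co_suspect = p$co_suspect,
      co_suspect_rate = p$co_suspect_rate %||% 0
    )
  })
  scenario_config(profiles = profiles, categories = cats,
                  background_vocab = unlist(y$background_vocab),
                  seed = y$seed %||% 1L)
}
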