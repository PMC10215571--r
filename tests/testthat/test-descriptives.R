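cats <- builtin_categories()

test_that("percent formatting rounds half away from zero at two decimals", {
  expect_equal(format_percent(83, 986), "8.42")
  expect_equal(format_percent(165, 319), "51.72")
  expect_equal(format_percent(1, 3), "33.33")
  expect_equal(format_percent(85, 100), "85.00")
  expect_equal(format_percent(1, 800), "0.13")   # 0.125 -> half away from zero
  expect_equal(format_percent(1, 8000), "0.01")  # 0.0125 -> 0.01
  expect_error(format_percent(1, 0), "positive")
})

test_that("percent strings re-parse to within 0.005 of the exact fraction", {
  set.seed(401)
  num <- sample(0:500, 200, replace = TRUE)
  den <- sample(1:5000, 200, replace = TRUE)
  reparsed <- as.numeric(format_percent(num, den))
  expect_true(all(abs(reparsed - 100 * num / den) <= 0.005 + 1e-9))
})

test_that("category membership is set-valued and alias-aware", {
  expect_true(case_in_category(c("Drug ineffective", "Nausea"), cats$DI))
  expect_false(case_in_category("Nausea", cats$DR))
  # two member PTs still make one case
  expect_equal(sum(case_in_category(
    list(c("Drug resistance", "Pathogen resistance")), cats$DR)), 1)
})

test_that("category_summary matches a brute-force per-case loop", {
  for (seed in c(21, 22, 23, 24)) {
    cases <- random_small_dataset(seed)
    for (drug in c("alpha", "beta")) {
      sub <- cases[vapply(cases$drugs, function(d) drug %in% d, logical(1)), ]
      if (nrow(sub) == 0) next
      for (cat in cats) {
        # oracle: explicit loop over cases and members
        n_oracle <- 0L
        fatal_oracle <- 0L
        for (i in seq_len(nrow(sub))) {
          rx <- tolower(trimws(sub$reactions[[i]]))
          rx[rx == "multi-drug resistance"] <- "multiple-drug resistance"
          if (length(intersect(rx, cat$members)) > 0) {
            n_oracle <- n_oracle + 1L
            if (sub$fatal[i]) fatal_oracle <- fatal_oracle + 1L
          }
        }
        cs <- category_summary(cases, drug, cat)
        expect_equal(cs$n_cases, n_oracle)
        expect_equal(cs$fatal_n, fatal_oracle)
        expect_equal(cs$n_total, nrow(sub))
        if (cs$n_cases > 0) {
          expect_true(all(cs$pt_breakdown$count <= cs$n_cases))
        }
      }
    }
  }
})

test_that("a case with two member PTs increments both PT rows but n_cases once", {
  cases <- icsr_dataset(
    case_id = c("a", "b"),
    drugs = list("colistin", "colistin"),
    reactions = list(c("Drug resistance", "Pathogen resistance"), "Nausea"),
    age_group = rep("18-64 years", 2), sex = rep("Male", 2),
    origin = rep("EEA", 2), reporter = rep("Healthcare professional", 2),
    fatal = c(FALSE, FALSE)
  )
  cs <- category_summary(cases, "colistin", cats$DR)
  expect_equal(cs$n_cases, 1)
  bd <- cs$pt_breakdown
  expect_equal(bd$count[bd$pt == "drug resistance"], 1)
  expect_equal(bd$count[bd$pt == "pathogen resistance"], 1)
})

test_that("published worked percentages are reproduced from their counts", {
  col <- category_summary(counted_fixture("COL", 986, 83, 100), "COL", cats$DR)
  expect_equal(col$percent, 8.42)
  di <- category_summary(counted_fixture("COL", 986, 83, 100), "COL", cats$DI)
  expect_equal(di$percent, 10.14)
  mer_di <- category_summary(counted_fixture("MER", 8864, 316, 838), "MER", cats$DI)
  expect_equal(mer_di$percent, 9.45)
  # PT-level share: 170 "drug resistance" of 316 MER DR cases
  mer_dr_cases <- icsr_dataset(
    case_id = sprintf("m%04d", 1:316),
    drugs = as.list(rep("MER", 316)),
    reactions = c(rep(list("Drug resistance"), 170),
                  rep(list("Pathogen resistance"), 146)),
    age_group = rep("18-64 years", 316), sex = rep("Male", 316),
    origin = rep("EEA", 316), reporter = rep("Healthcare professional", 316),
    fatal = rep(FALSE, 316)
  )
  cs <- category_summary(mer_dr_cases, "MER", cats$DR)
  bd <- cs$pt_breakdown
  expect_equal(bd$percent[bd$pt == "drug resistance"], 53.80)
})

test_that("zero category cases yield an empty breakdown and undefined fatal share", {
  cs <- category_summary(counted_fixture("X", 10, 0, 0), "X", cats$DR)
  expect_equal(cs$n_cases, 0)
  expect_equal(nrow(cs$pt_breakdown), 0)
  expect_true(is.na(cs$fatal_percent))
  expect_error(category_summary(counted_fixture("X", 5, 0, 0), "Y", cats$DR),
               "no cases")
})

test_that("stratified distributions use fixed stratum order and exact shares", {
  cases <- icsr_dataset(
    case_id = paste0("c", 1:4),
    drugs = as.list(rep("d", 4)),
    reactions = rep(list("Nausea"), 4),
    age_group = rep("18-64 years", 4),
    sex = c("Male", "Male", "Female", "zzz"),
    origin = rep("EEA", 4),
    reporter = rep("Healthcare professional", 4),
    fatal = rep(FALSE, 4)
  )
  tab <- distribution_by(cases, "sex")
  expect_equal(tab$stratum, c("Female", "Male", "Not specified"))
  expect_equal(tab$count, c(1L, 2L, 1L))
  expect_equal(tab$percent, c(25, 50, 25))
  expect_equal(sum(tab$count), nrow(cases))
  expect_true(abs(sum(tab$percent) - 100) <= 0.05)

  age <- distribution_by(cases, "age_group")
  expect_equal(age$stratum, icsr_age_groups())
  expect_equal(sum(age$count), 4)

  empty <- distribution_by(cases[0, ], "origin")
  expect_equal(empty$count, c(0L, 0L, 0L))
  expect_true(all(is.na(empty$percent)))
})

test_that("empirical stratum shares track known sampling weights", {
  n <- 4000L
  p_male <- 0.55
  prof <- drug_profile(
    "simdrug", n, c(DR = 0.05),
    list(DR = c("drug resistance" = 1)),
    c(DR = 0.2), 0.05,
    demographics = list(
      age_group = c("18-64 years" = 0.6, "65-85 years" = 0.4),
      sex = c(Male = p_male, Female = 1 - p_male),
      origin = c(EEA = 0.7, "Non-EEA" = 0.3),
      reporter = c("Healthcare professional" = 0.9,
                   "Non-healthcare professional" = 0.1)
    )
  )
  cases <- generate_cases(scenario_config(list(prof), seed = 99L))
  tab <- distribution_by(cases, "sex")
  phat <- tab$count[tab$stratum == "Male"] / n
  expect_lt(abs(phat - p_male), 3 * sqrt(p_male * (1 - p_male) / n))
  tab <- distribution_by(cases, "origin")
  phat <- tab$count[tab$stratum == "EEA"] / n
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})
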