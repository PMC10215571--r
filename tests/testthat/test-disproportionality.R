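cats <- builtin_categories()

test_that("contingency cells match manual enumeration of a 30-case fixture", {
  cases <- two_arm_fixture(n_target = 10, k_target = 4,
                           n_comparator = 20, k_comparator = 2)
  tab <- build_contingency(cases, "drugA", "drugB", cats$DR)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(4, 6, 2, 18))
  expect_false(tab$corrected)
  expect_equal(tab$n_reports, 4)
})

test_that("contingency construction equals a brute-force per-case loop", {
  for (seed in c(31, 32, 33)) {
    cases <- random_small_dataset(seed)
    has_alpha <- any(vapply(cases$drugs, function(d) "alpha" %in% d, logical(1)))
    has_beta <- any(vapply(cases$drugs, function(d) "beta" %in% d, logical(1)))
    if (!has_alpha || !has_beta) next
    for (cat in cats) {
      a <- b <- c_ <- d <- 0L
      for (i in seq_len(nrow(cases))) {
        rx <- tolower(trimws(cases$reactions[[i]]))
        rx[rx == "multi-drug resistance"] <- "multiple-drug resistance"
        hit <- length(intersect(rx, cat$members)) > 0
        if ("alpha" %in% cases$drugs[[i]]) {
          if (hit) a <- a + 1L else b <- b + 1L
        }
        if ("beta" %in% cases$drugs[[i]]) {
          if (hit) c_ <- c_ + 1L else d <- d + 1L
        }
      }
      tab <- build_contingency(cases, "alpha", "beta", cat)
      raw <- c(tab$a, tab$b, tab$c, tab$d) - if (tab$corrected) 0.5 else 0
      expect_equal(raw, c(a, b, c_, d))
    }
  }
})

test_that("a case naming both drugs contributes to both margins", {
  cases <- icsr_dataset(
    case_id = c("x1", "x2", "x3"),
    drugs = list(c("A", "B"), "A", "B"),
    reactions = list("Drug resistance", "Nausea", "Nausea"),
    age_group = rep("18-64 years", 3), sex = rep("Male", 3),
    origin = rep("EEA", 3), reporter = rep("Healthcare professional", 3),
    fatal = rep(FALSE, 3)
  )
  # x1 (in DR) names both drugs, so it lands in both a and c
  tab <- build_contingency(cases, "A", "B", cats$DR)
  expect_false(tab$corrected)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))
})

test_that("zero-cell policies behave as configured", {
  cases <- two_arm_fixture(n_target = 6, k_target = 2,
                           n_comparator = 12, k_comparator = 0)
  tab <- build_contingency(cases, "drugA", "drugB", cats$DR, policy = "haldane")
  expect_true(tab$corrected)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2.5, 4.5, 0.5, 12.5))
  expect_equal(tab$n_reports, 2)
  expect_error(
    build_contingency(cases, "drugA", "drugB", cats$DR, policy = "error"),
    "zero cell"
  )
  expect_error(build_contingency(cases, "drugA", "nosuch", cats$DR),
               "missing-drug")
  expect_error(build_contingency(cases, "drugA", "druga", cats$DR), "differ")
})

test_that("the ROR engine reproduces hand-computed tables", {
  r <- compute_ror(c(1, 1, 1, 1))
  expect_equal(r$ror, 1)
  expect_equal(r$p_value, 1)
  expect_equal(r$ci_low * r$ci_high, 1, tolerance = 1e-12)

  r <- compute_ror(c(4, 6, 2, 18))
  expect_equal(r$ror, 6)
  expect_equal(r$se_ln, sqrt(35 / 36))
  expect_equal(r$ci_low, exp(log(6) - 1.96 * sqrt(35 / 36)))
  expect_equal(r$ci_high, exp(log(6) + 1.96 * sqrt(35 / 36)))
  expect_equal(r$ci_low, 0.868, tolerance = 1e-3)
  expect_equal(r$ci_high, 41.44, tolerance = 1e-3)

  # Haldane-corrected cells taken as-is
  r <- compute_ror(c(5.5, 5.5, 0.5, 10.5))
  expect_equal(r$ror, 21)
  expect_equal(r$n_reports, 5)

  expect_error(compute_ror(c(0, 1, 1, 1)), "positive")
})

test_that("log-ROR and its SE agree with an independent binomial glm fit", {
  for (cells in list(c(4, 6, 2, 18), c(12, 88, 7, 193), c(30, 470, 55, 445))) {
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    fit <- stats::glm(cbind(c(a, c_), c(b, d)) ~ c(1, 0), family = stats::binomial())
    est <- summary(fit)$coefficients[2, ]
    r <- compute_ror(cells)
    expect_equal(log(r$ror), unname(est["Estimate"]), tolerance = 1e-6)
    expect_equal(r$se_ln, unname(est["Std. Error"]), tolerance = 1e-6)
  }
})

test_that("reciprocity, monotonicity, and CI geometry hold on random tables", {
  set.seed(501)
  for (i in 1:1000) {
    cells <- sample(1:200, 4, replace = TRUE)
    r <- compute_ror(cells)
    r_swap <- compute_ror(cells[c(3, 4, 1, 2)])
    expect_equal(r$ror * r_swap$ror, 1, tolerance = 1e-10)
    expect_equal(r$ci_low * r_swap$ci_high, 1, tolerance = 1e-8)
    expect_true(r$ci_low <= r$ror && r$ror <= r$ci_high)
    # increasing a strictly increases the ROR
    r_up <- compute_ror(cells + c(1, 0, 0, 0))
    expect_gt(r_up$ror, r$ror)
  }
  # CI narrows (on the log scale) as all cells scale up
  r1 <- compute_ror(c(4, 6, 2, 18))
  r10 <- compute_ror(10 * c(4, 6, 2, 18))
  expect_lt(log(r10$ci_high / r10$ci_low), log(r1$ci_high / r1$ci_low))
})

test_that("significance stars follow the ladder printed on screen reports", {
  expect_equal(significance_stars(c(0.2, 0.049, 0.01, 0.001, 0.0001, 2e-5)),
               c("", "*", "**", "***", "****", "****"))
})

test_that("the signal rule needs at least five reports and a lower CI above 1", {
  mk <- function(n, lo) structure(list(n_reports = n, ci_low = lo),
                                  class = "ror_result")
  expect_false(detect_signal(mk(4, 3.0)))
  expect_true(detect_signal(mk(5, 1.0001)))
  expect_false(detect_signal(mk(50, 0.999)))
  expect_false(detect_signal(mk(50, 1.0)))
  expect_true(detect_signal(mk(83, 12.5741)))
})

test_that("screen emits the full cartesian product in config order", {
  cases <- dplyr::bind_rows(
    counted_fixture("T1", 50, 10, 5),
    counted_fixture("T2", 60, 5, 10),
    counted_fixture("C1", 80, 4, 4),
    counted_fixture("C2", 90, 2, 8)
  )
  class(cases) <- c("icsr_tbl", class(cases))
  cfg <- run_config(c("T1", "T2"), c("C1", "C2"))
  s <- screen(cases, cfg)
  expect_equal(nrow(s), 8)
  expect_equal(unique(s$target), c("T1", "T2"))
  expect_true(all(s$available))
  # composition identity against the single-pair path
  tab <- build_contingency(cases, "T1", "C1", cats$DR)
  r <- compute_ror(tab)
  row <- s[s$target == "T1" & s$comparator == "C1" & s$category == "DR", ]
  expect_equal(row$ror, r$ror)
  expect_equal(row$ci_low, r$ci_low)
  expect_equal(row$signal, r$signal)
  expect_equal(c(row$a, row$b, row$c, row$d), c(tab$a, tab$b, tab$c, tab$d))
})

test_that("a missing comparator yields an unavailable row, not an abort", {
  cases <- counted_fixture("T1", 30, 6, 3)
  cfg <- run_config("T1", c("ghost", "T2"))
  cases <- dplyr::bind_rows(cases, counted_fixture("T2", 30, 3, 3))
  class(cases) <- c("icsr_tbl", class(cases))
  w <- capture_warnings(s <- screen(cases, cfg))
  expect_length(w, 2)  # one per category of the absent comparator
  expect_match(w, "unavailable", all = TRUE)
  expect_equal(nrow(s), 4)
  expect_false(any(s$available[s$comparator == "ghost"]))
  expect_true(all(s$available[s$comparator == "T2"]))
})
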