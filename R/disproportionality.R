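#' Build the 2x2 contingency table for one (target, comparator, category)
#'
#' `a` = target-drug cases reporting at least one category PT, `b` = the
#' remaining target-drug cases, `c`/`d` likewise for the comparator. A case
#' naming both drugs as suspected contributes to both margins. If any cell is
#' zero and `policy = "haldane"`, 0.5 is added to all four cells
#' (Haldane-Anscombe) and the table is flagged `corrected`; with
#' `policy = "error"` a zero cell is an error.
#'
#' @param cases An ICSR dataset.
#' @param target,comparator Distinct drug tokens; a comparator absent from
#'   the dataset is a missing-drug error.
#' @param category An [adr_category()].
#' @param policy `"haldane"` or `"error"`.
#' @return An object of class `contingency_2x2`: effective cells `a`, `b`,
#'   `c`, `d`, flag `corrected`, `n_reports` (the uncorrected `a`), and the
#'   identifying `target`, `comparator`, `category`.
#' @export
build_contingency <- function(cases, target, comparator, category,
                              policy = c("haldane", "error")) {
  policy <- match.arg(policy)
  if (drug_normalize(target) == drug_normalize(comparator)) {
    stop("target and comparator must differ", call. = FALSE)
  }
  build_contingency_from_subsets(
    cases_for_drug(cases, target), cases_for_drug(cases, comparator),
    target, comparator, category, policy
  )
}

build_contingency_from_subsets <- function(tgt, cmp, target, comparator,
                                           category, policy) {
  if (nrow(cmp) == 0L) {
    stop("missing-drug: comparator '", comparator, "' absent from dataset",
         call. = FALSE)
  }
  a <- sum(case_in_category(tgt, category))
  b <- nrow(tgt) - a
  c <- sum(case_in_category(cmp, category))
  d <- nrow(cmp) - c
  corrected <- FALSE
  cells <- c(a, b, c, d)
  if (any(cells == 0)) {
    if (policy == "error") {
      stop("zero cell in contingency table (a=", a, ", b=", b, ", c=", c,
           ", d=", d, ")", call. = FALSE)
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  structure(list(
    a = cells[1], b = cells[2], c = cells[3], d = cells[4],
    corrected = corrected, n_reports = a,
    target = target, comparator = comparator, category = category$name
  ), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2> %s vs %s / %s: a=%g b=%g c=%g d=%g%s\n",
              x$target, x$comparator, x$category, x$a, x$b, x$c, x$d,
              if (x$corrected) " (Haldane-corrected)" else ""))
  invisible(x)
}

significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else
    if (pi <= 1e-4) "****" else
    if (pi <= 1e-3) "***" else
    if (pi <= 1e-2) "**" else
    if (pi <  0.05) "*" else ""
  }, character(1))
}

#' Reporting odds ratio with Wald confidence interval
#'
#' ROR = (a d)/(b c); the standard error of log ROR is
#' sqrt(1/a + 1/b + 1/c + 1/d) and the CI is
#' exp(ln ROR +/- z * SE). For `alpha = 0.05` the multiplier is fixed at
#' exactly 1.96 (the value conventionally printed); other levels use the
#' exact normal quantile. The p-value is the two-sided normal tail of
#' ln(ROR)/SE, and significance stars follow the usual ladder
#' (* p < 0.05, ** p <= 0.01, *** p <= 0.001, **** p <= 0.0001).
#'
#' @param table A `contingency_2x2` from [build_contingency()], or a numeric
#'   vector `c(a, b, c, d)` of (possibly Haldane-corrected) cells.
#' @param alpha Two-sided level; default 0.05.
#' @return An object of class `ror_result`: `ror`, `se_ln`, `ci_low`,
#'   `ci_high`, `p_value`, `n_reports`, `signal`, `stars`.
#' @examples
#' compute_ror(c(4, 6, 2, 18))
#' @export
compute_ror <- function(table, alpha = 0.05) {
  if (inherits(table, "contingency_2x2")) {
    cells <- c(table$a, table$b, table$c, table$d)
    n_reports <- table$n_reports
  } else {
    cells <- as.numeric(table)
    stopifnot(length(cells) == 4L)
    # for bare corrected cells, reports are the uncorrected count
    n_reports <- if (cells[1] == floor(cells[1])) cells[1] else cells[1] - 0.5
  }
  if (any(cells <= 0)) {
    stop("all contingency cells must be positive; apply a zero-cell policy first",
         call. = FALSE)
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  ror <- (a * d) / (b * c)
  se_ln <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- if (isTRUE(all.equal(alpha, 0.05))) 1.96 else stats::qnorm(1 - alpha / 2)
  ci_low <- exp(log(ror) - z * se_ln)
  ci_high <- exp(log(ror) + z * se_ln)
  p_value <- 2 * stats::pnorm(-abs(log(ror) / se_ln))
  res <- structure(list(
    ror = ror, se_ln = se_ln, ci_low = ci_low, ci_high = ci_high,
    p_value = p_value, n_reports = n_reports,
    signal = NA, stars = significance_stars(p_value)
  ), class = "ror_result")
  res$signal <- detect_signal(res)
  res
}

#' @export
print.ror_result <- function(x, ...) {
  cat(sprintf("<ror_result> ROR %.4f (95%% CI %.4f-%.4f), p=%.3g%s, n=%g, %s\n",
              x$ror, x$ci_low, x$ci_high, x$p_value,
              if (nzchar(x$stars)) paste0(" ", x$stars) else "",
              x$n_reports,
              if (x$signal) "SIGNAL" else "no signal"))
  invisible(x)
}

#' Signal of disproportionate reporting
#'
#' A signal is assumed only when at least five reports underlie the target
#' cell and the 95% CI of the ROR lies entirely above 1 (lower bound > 1);
#' fewer than five reports, or a lower bound at or below 1, is no signal.
#'
#' @param result A `ror_result`.
#' @return Logical.
#' @export
detect_signal <- function(result) {
  isTRUE(result$n_reports >= 5 && result$ci_low > 1.0)
}

#' Disproportionality screen over a run configuration
#'
#' Computes, for every (target, comparator, category) triple in config order,
#' the 2x2 table, the ROR with CI and p-value, and the signal flag. A
#' comparator absent from the dataset does not abort the screen: its rows are
#' emitted with `available = FALSE` and NA statistics, with a warning.
#'
#' @param cases An ICSR dataset.
#' @param config A [run_config()].
#' @return A tibble with one row per triple: `target`, `comparator`,
#'   `category`, `a`, `b`, `c`, `d`, `corrected`, `n_reports`, `ror`,
#'   `ci_low`, `ci_high`, `p_value`, `stars`, `signal`, `available`.
#' @export
screen <- function(cases, config) {
  stopifnot(inherits(config, "run_config"))
  grid <- expand.grid(
    category = names(config$categories),
    comparator = config$comparator_drugs,
    target = config$target_drugs,
    stringsAsFactors = FALSE
  )[, c("target", "comparator", "category")]
  if (nrow(grid) == 0L) {
    return(tibble::tibble(
      target = character(), comparator = character(), category = character(),
      a = numeric(), b = numeric(), c = numeric(), d = numeric(),
      corrected = logical(), n_reports = numeric(), ror = numeric(),
      ci_low = numeric(), ci_high = numeric(), p_value = numeric(),
      stars = character(), signal = logical(), available = logical()
    ))
  }
  # scan the dataset once per drug, not once per screen row
  all_drugs <- unique(c(config$target_drugs, config$comparator_drugs))
  subsets <- lapply(all_drugs, function(d) cases_for_drug(cases, d))
  names(subsets) <- drug_normalize(all_drugs)
  rows <- purrr::pmap(grid, function(target, comparator, category) {
    cat_obj <- config$categories[[category]]
    tab <- tryCatch(
      build_contingency_from_subsets(
        subsets[[drug_normalize(target)]], subsets[[drug_normalize(comparator)]],
        target, comparator, cat_obj, policy = config$zero_cell_policy
      ),
      error = function(e) e
    )
    if (inherits(tab, "error")) {
      warning("screen row unavailable (", target, " vs ", comparator, " / ",
              category, "): ", conditionMessage(tab), call. = FALSE)
      return(tibble::tibble(
        target = target, comparator = comparator, category = category,
        a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
        corrected = NA, n_reports = NA_real_, ror = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
        stars = "", signal = NA, available = FALSE
      ))
    }
    r <- compute_ror(tab, alpha = config$alpha)
    tibble::tibble(
      target = target, comparator = comparator, category = category,
      a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      corrected = tab$corrected, n_reports = as.numeric(tab$n_reports),
      ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
      p_value = r$p_value, stars = r$stars, signal = r$signal,
      available = TRUE
    )
  })
  dplyr::bind_rows(rows)
}
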