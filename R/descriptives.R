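#' Percentages rendered the way ADR portals print them
#'
#' `percent_value()` computes `100 * numerator / denominator` rounded
#' half-away-from-zero to two decimals; `format_percent()` renders it with
#' trailing zeros kept (`"8.42"`, `"85.00"`).
#'
#' @param numerator Integer count.
#' @param denominator Positive integer total.
#' @return `percent_value()` a numeric; `format_percent()` a character.
#' @examples
#' format_percent(83, 986)  # "8.42"
#' format_percent(1, 3)     # "33.33"
#' @export
percent_value <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("percent denominator must be positive", call. = FALSE)
  }
  v <- 100 * numerator / denominator
  # half-away-from-zero at 2 decimals; eps guards binary representation of
  # exact halves such as 12.5
  sign(v) * floor(abs(v) * 100 + 0.5 + 1e-9) / 100
}

#' @rdname percent_value
#' @export
format_percent <- function(numerator, denominator) {
  sprintf("%.2f", percent_value(numerator, denominator))
}

#' Does a case fall in an ADR category?
#'
#' A case is in a category iff its reaction set intersects the category's
#' member PTs, after normalization and alias resolution. A case with several
#' member PTs is still one case.
#'
#' @param reactions A character vector of reaction PTs (one case) or a list
#'   of such vectors / an ICSR dataset.
#' @param category An [adr_category()].
#' @return Logical, one element per case.
#' @export
case_in_category <- function(reactions, category) {
  stopifnot(inherits(category, "adr_category"))
  if (is.data.frame(reactions)) reactions <- reactions$reactions
  if (is.character(reactions)) reactions <- list(reactions)
  n <- length(reactions)
  idx <- rep.int(seq_len(n), lengths(reactions))
  hit <- pt_canonical(unlist(reactions, use.names = FALSE)) %in% category$members
  out <- logical(n)
  out[idx[hit]] <- TRUE
  out
}

#' Category summary for one drug
#'
#' Counts, within the ICSRs naming `drug` as suspected, the cases reporting
#' at least one member PT of `category`, the fatal fraction among those
#' cases, and the per-PT breakdown (a case carrying two member PTs increments
#' both PT rows but is counted once in `n_cases`).
#'
#' @param cases An ICSR dataset (any drugs; filtered internally).
#' @param drug Drug token.
#' @param category An [adr_category()].
#' @return A list of class `category_summary`: `drug`, `category`, `n_cases`,
#'   `n_total`, `percent`, `fatal_n`, `fatal_percent` (NA when `n_cases` is
#'   0), and `pt_breakdown`, a tibble with columns `pt`, `count`, `percent`
#'   (of `n_cases`).
#' @export
category_summary <- function(cases, drug, category) {
  drug_cases <- cases_for_drug(cases, drug)
  n_total <- nrow(drug_cases)
  if (n_total == 0L) {
    stop("no cases name drug '", drug, "'; percentages undefined", call. = FALSE)
  }
  in_cat <- case_in_category(drug_cases, category)
  n_cases <- sum(in_cat)
  fatal_n <- sum(drug_cases$fatal & in_cat)
  canon <- lapply(drug_cases$reactions[in_cat], pt_canonical)
  pt_counts <- vapply(category$members,
                      function(m) sum(vapply(canon, function(r) m %in% r, logical(1))),
                      integer(1))
  breakdown <- tibble::tibble(
    pt = category$members,
    count = unname(pt_counts),
    percent = if (n_cases > 0) percent_value(unname(pt_counts), n_cases) else NA_real_
  )
  if (n_cases == 0L) breakdown <- breakdown[0, ]
  structure(list(
    drug = drug, category = category$name,
    n_cases = n_cases, n_total = n_total,
    percent = percent_value(n_cases, n_total),
    fatal_n = fatal_n,
    fatal_percent = if (n_cases > 0) percent_value(fatal_n, n_cases) else NA_real_,
    pt_breakdown = breakdown
  ), class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat(sprintf("<category_summary> %s / %s: %d of %d cases (%.2f%%), %s fatal\n",
              x$drug, x$category, x$n_cases, x$n_total, x$percent,
              if (is.na(x$fatal_percent)) "-" else sprintf("%.2f%%", x$fatal_percent)))
  print(x$pt_breakdown)
  invisible(x)
}

#' Stratified descriptive table
#'
#' Distribution of an ICSR dataset over one of the four stratifiers, in fixed
#' stratum order (EMA age-band order; Female/Male; EEA/Non-EEA; healthcare /
#' non-healthcare professional; `"Not specified"` last). Every stratum
#' appears even at count zero.
#'
#' @param cases An ICSR dataset.
#' @param variable One of `"age_group"`, `"sex"`, `"origin"`, `"reporter"`.
#' @return A tibble with columns `stratum`, `count`, `percent` (NA for an
#'   empty dataset).
#' @export
distribution_by <- function(cases, variable = c("age_group", "sex", "origin",
                                                "reporter")) {
  variable <- match.arg(variable)
  levels <- icsr_levels_for(variable)
  counts <- table(factor(cases[[variable]], levels = levels))
  n <- nrow(cases)
  tibble::tibble(
    stratum = levels,
    count = as.integer(counts),
    percent = if (n > 0) percent_value(as.integer(counts), n) else NA_real_
  )
}
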