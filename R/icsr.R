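#' @importFrom rlang %||% .data
NULL

#' Closed level sets for ICSR stratifiers
#'
#' EMA age bands, sex, geographic origin and reporter group as exposed by
#' public ADR portals. Unrecognized tokens coerce to `"Not specified"` on
#' read.
#'
#' @name icsr-levels
#' @examples
#' icsr_age_groups()
NULL

#' @rdname icsr-levels
#' @export
icsr_age_groups <- function() {
  c("0-1 month", "2 months-2 years", "3-11 years", "12-17 years",
    "18-64 years", "65-85 years", ">85 years", "Not specified")
}

#' @rdname icsr-levels
#' @export
icsr_sexes <- function() c("Female", "Male", "Not specified")

#' @rdname icsr-levels
#' @export
icsr_origins <- function() c("EEA", "Non-EEA", "Not specified")

#' @rdname icsr-levels
#' @export
icsr_reporters <- function() {
  c("Healthcare professional", "Non-healthcare professional", "Not specified")
}

icsr_levels_for <- function(variable) {
  switch(variable,
    age_group = icsr_age_groups(),
    sex       = icsr_sexes(),
    origin    = icsr_origins(),
    reporter  = icsr_reporters(),
    stop("unknown stratifier: ", variable, call. = FALSE)
  )
}

icsr_not_specified <- "Not specified"

# Match a raw portal token against a closed level set, case-insensitively and
# whitespace-normalized; anything unmatched becomes "Not specified".
coerce_level <- function(x, levels) {
  key <- pt_normalize(x)
  lookup <- stats::setNames(levels, pt_normalize(levels))
  out <- unname(lookup[key])
  out[is.na(out) | !nzchar(key)] <- icsr_not_specified
  out
}

drug_normalize <- function(x) pt_normalize(x)

#' Assemble an ICSR dataset
#'
#' Builds the tibble representation used everywhere in the package: one row
#' per Individual Case Safety Report, with `drugs` and `reactions` held as
#' list-columns of character vectors (sets of suspected-drug tokens and of
#' MedDRA preferred terms).
#'
#' @param case_id Character vector of unique case identifiers.
#' @param drugs List of non-empty character vectors (suspected drugs), or a
#'   character vector for single-drug cases.
#' @param reactions List of non-empty character vectors of reaction PTs.
#' @param age_group,sex,origin,reporter Character vectors drawn from the
#'   closed level sets (see [icsr_age_groups()] and friends); unrecognized
#'   values are coerced to `"Not specified"`.
#' @param fatal Logical vector: case-level fatal-outcome flag.
#' @return A tibble of class `icsr_tbl`.
#' @export
icsr_dataset <- function(case_id, drugs, reactions, age_group, sex, origin,
                         reporter, fatal) {
  n <- length(case_id)
  if (is.character(drugs)) drugs <- as.list(drugs)
  stopifnot(length(drugs) == n, length(reactions) == n, length(fatal) == n)
  if (anyDuplicated(case_id)) {
    stop("duplicate case_id: ",
         paste(unique(case_id[duplicated(case_id)]), collapse = ", "),
         call. = FALSE)
  }
  empty_drug <- vapply(drugs, function(d) length(d) == 0L || all(!nzchar(trimws(d))), logical(1))
  empty_rxn  <- vapply(reactions, function(r) length(r) == 0L || all(!nzchar(trimws(r))), logical(1))
  if (any(empty_drug)) {
    stop("empty drugs for case(s): ", paste(case_id[empty_drug], collapse = ", "),
         call. = FALSE)
  }
  if (any(empty_rxn)) {
    stop("empty reactions for case(s): ", paste(case_id[empty_rxn], collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    case_id   = as.character(case_id),
    drugs     = lapply(drugs, function(d) unique(trimws(d))),
    reactions = lapply(reactions, function(r) unique(trimws(r))),
    age_group = coerce_level(age_group, icsr_age_groups()),
    sex       = coerce_level(sex, icsr_sexes()),
    origin    = coerce_level(origin, icsr_origins()),
    reporter  = coerce_level(reporter, icsr_reporters()),
    fatal     = as.logical(fatal)
  )
  class(out) <- c("icsr_tbl", class(out))
  out
}

# Trusted constructor: inputs already cleaned and levels already valid
# (generator path); skips the per-case normalization of icsr_dataset().
new_icsr_tbl <- function(case_id, drugs, reactions, age_group, sex, origin,
                         reporter, fatal) {
  out <- tibble::tibble(
    case_id = case_id, drugs = drugs, reactions = reactions,
    age_group = age_group, sex = sex, origin = origin,
    reporter = reporter, fatal = fatal
  )
  class(out) <- c("icsr_tbl", class(out))
  out
}

#' Restrict an ICSR dataset to cases naming a suspected drug
#'
#' Drug tokens are matched case-insensitively after whitespace normalization.
#' A case co-reporting several suspected drugs belongs to every one of them.
#'
#' @param cases An ICSR dataset from [icsr_dataset()] or [read_linelist()].
#' @param drug Drug token.
#' @return The subset of `cases` naming `drug`.
#' @export
cases_for_drug <- function(cases, drug) {
  key <- drug_normalize(drug)
  sizes <- lengths(cases$drugs)
  idx <- rep.int(seq_len(nrow(cases)), sizes)
  hit <- drug_normalize(unlist(cases$drugs, use.names = FALSE)) == key
  keep <- logical(nrow(cases))
  keep[idx[hit]] <- TRUE
  cases[keep, , drop = FALSE]
}
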