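linelist_columns <- c("case_id", "drugs", "reactions", "age_group", "sex",
                      "origin", "reporter", "fatal")

# Reactions and drugs cells are sub-delimited with ";" because commas occur
# inside PT labels ("drug ineffective for unapproved indication" never does,
# but combination-product names do).
split_cell <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  lapply(parts, function(p) {
    p <- trimws(p)
    p[nzchar(p)]
  })
}

join_cell <- function(x) {
  vapply(x, function(p) paste(p, collapse = "; "), character(1))
}

#' Read an ICSR line-list
#'
#' Reads a delimited UTF-8 line-list (one row per case; `drugs` and
#' `reactions` cells are semicolon-separated sets) into an ICSR dataset.
#' Blank or unrecognized tokens in `age_group`, `sex`, `origin` or `reporter`
#' are mapped to `"Not specified"` with a warning naming the affected column;
#' duplicate `case_id` values or empty `drugs`/`reactions` cells are errors.
#'
#' @param path Path to the line-list file.
#' @param delim Field delimiter (default comma).
#' @return An ICSR dataset ([icsr_dataset()]); zero rows for a header-only
#'   file.
#' @export
read_linelist <- function(path, delim = ",") {
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    quote = "\"", na = character(), progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(linelist_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("line-list is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(icsr_dataset(character(), list(), list(), character(), character(),
                        character(), character(), logical()))
  }
  for (col in c("age_group", "sex", "origin", "reporter")) {
    coerced <- coerce_level(raw[[col]], icsr_levels_for(col))
    newly_ns <- coerced == icsr_not_specified &
      pt_normalize(raw[[col]]) != pt_normalize(icsr_not_specified) &
      nzchar(trimws(raw[[col]]))
    if (any(newly_ns)) {
      warning(sum(newly_ns), " unrecognized ", col, " value(s) coerced to '",
              icsr_not_specified, "'", call. = FALSE)
    }
  }
  fatal <- pt_normalize(raw$fatal) %in% c("true", "t", "1", "yes", "fatal")
  icsr_dataset(
    case_id   = raw$case_id,
    drugs     = split_cell(raw$drugs),
    reactions = split_cell(raw$reactions),
    age_group = raw$age_group,
    sex       = raw$sex,
    origin    = raw$origin,
    reporter  = raw$reporter,
    fatal     = fatal
  )
}

#' Write an ICSR line-list
#'
#' Deterministic inverse of [read_linelist()]: fixed column order, rows sorted
#' by `case_id` (C locale), `drugs`/`reactions` joined with `"; "`, `fatal`
#' rendered `true`/`false`. Writing the same dataset twice yields
#' byte-identical files.
#'
#' @param cases An ICSR dataset.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_linelist <- function(cases, path, delim = ",") {
  stopifnot(!anyDuplicated(cases$case_id))
  ord <- order(cases$case_id, method = "radix")
  flat <- tibble::tibble(
    case_id   = cases$case_id[ord],
    drugs     = join_cell(cases$drugs[ord]),
    reactions = join_cell(cases$reactions[ord]),
    age_group = cases$age_group[ord],
    sex       = cases$sex[ord],
    origin    = cases$origin[ord],
    reporter  = cases$reporter[ord],
    fatal     = ifelse(cases$fatal[ord], "true", "false")
  )
  readr::write_delim(flat, path, delim = delim, quote = "needed", eol = "\n",
                     progress = FALSE)
  invisible(path)
}
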