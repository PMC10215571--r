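#' Normalize MedDRA preferred-term labels
#'
#' Public ADR portals print preferred terms (PTs) with inconsistent
#' capitalization ("Drug resistance" vs "drug resistance"), so all set
#' membership in this package is decided on a normalized form: lowercased,
#' trimmed, with internal whitespace runs collapsed to single spaces.
#'
#' @param x Character vector of PT labels.
#' @return Character vector of normalized labels.
#' @examples
#' pt_normalize(c("  Drug   Ineffective ", "drug ineffective"))
#' @export
pt_normalize <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# One PT is printed under two spellings in portal exports; both map to the
# same canonical member.
pt_alias_table <- c(
  "multi-drug resistance" = "multiple-drug resistance"
)

#' Canonical form of preferred-term labels
#'
#' Applies [pt_normalize()] and then resolves registered spelling aliases
#' (currently "multi-drug resistance" -> "multiple-drug resistance") so that
#' variant spellings of one PT compare equal.
#'
#' @param x Character vector of PT labels.
#' @return Character vector of canonical labels.
#' @export
pt_canonical <- function(x) {
  x <- pt_normalize(x)
  hit <- x %in% names(pt_alias_table)
  x[hit] <- unname(pt_alias_table[x[hit]])
  x
}

#' Construct an ADR category (a named preferred-term query set)
#'
#' @param name Category name, e.g. `"DR"` or `"DI"`.
#' @param members Character vector of member PT labels; stored canonicalized,
#'   must be non-empty and duplicate-free after canonicalization.
#' @return An object of class `adr_category` with elements `name` and
#'   `members`.
#' @examples
#' adr_category("nephro", c("Acute kidney injury", "Renal failure"))
#' @export
adr_category <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(trimws(name)))
  members <- pt_canonical(members)
  if (length(members) == 0L || any(!nzchar(members))) {
    stop("category members must be non-empty preferred terms", call. = FALSE)
  }
  if (anyDuplicated(members)) {
    stop("duplicate category members after normalization: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, members = members), class = "adr_category")
}

#' @export
print.adr_category <- function(x, ...) {
  cat("<adr_category> ", x$name, " (", length(x$members), " PTs)\n", sep = "")
  cat(paste0("  - ", x$members, collapse = "\n"), "\n")
  invisible(x)
}

#' Built-in drug-resistance and drug-ineffectiveness query sets
#'
#' The two MedDRA preferred-term sets used throughout antimicrobial-resistance
#' pharmacovigilance surveillance: three PTs flagging drug resistance (DR) and
#' nine PTs flagging drug ineffectiveness (DI).
#'
#' @return A named list of two [adr_category()] objects, `DR` and `DI`.
#' @examples
#' builtin_categories()
#' @export
builtin_categories <- function() {
  list(
    DR = adr_category("DR", c(
      "drug resistance",
      "multiple-drug resistance",
      "pathogen resistance"
    )),
    DI = adr_category("DI", c(
      "therapeutic product effect decreased",
      "therapeutic product effect incomplete",
      "decreased activity",
      "drug ineffective for unapproved indication",
      "therapeutic product ineffective",
      "therapeutic response decreased",
      "treatment failure",
      "therapy non-responder",
      "drug ineffective"
    ))
  )
}
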