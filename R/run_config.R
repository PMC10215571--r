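#' Run configuration for a disproportionality screen
#'
#' Names the target and comparator drugs, the ADR categories to screen, the
#' zero-cell policy, the significance level and the seed for any stochastic
#' stage.
#'
#' @param target_drugs Character vector of target drug tokens.
#' @param comparator_drugs Character vector of comparator drug tokens;
#'   must be disjoint from `target_drugs` (tokens compared case-insensitively).
#' @param categories List of [adr_category()] objects; defaults to the
#'   built-in DR and DI query sets.
#' @param zero_cell_policy `"haldane"` (add 0.5 to all four cells of a 2x2
#'   table containing a zero) or `"error"`.
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @param seed Integer seed for stochastic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(target_drugs, comparator_drugs,
                       categories = builtin_categories(),
                       zero_cell_policy = c("haldane", "error"),
                       alpha = 0.05, seed = 1L) {
  zero_cell_policy <- match.arg(zero_cell_policy)
  stopifnot(is.character(target_drugs), length(target_drugs) >= 1L,
            is.character(comparator_drugs),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  overlap <- intersect(drug_normalize(target_drugs),
                       drug_normalize(comparator_drugs))
  if (length(overlap) > 0L) {
    stop("target and comparator drug lists must be disjoint; shared: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (!all(vapply(categories, inherits, logical(1), "adr_category"))) {
    stop("categories must be adr_category objects", call. = FALSE)
  }
  names(categories) <- vapply(categories, `[[`, character(1), "name")
  structure(
    list(target_drugs = target_drugs, comparator_drugs = comparator_drugs,
         categories = categories, zero_cell_policy = zero_cell_policy,
         alpha = alpha, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n",
      " targets:     ", paste(x$target_drugs, collapse = ", "), "\n",
      " comparators: ", paste(x$comparator_drugs, collapse = ", "), "\n",
      " categories:  ", paste(names(x$categories), collapse = ", "), "\n",
      " zero-cell:   ", x$zero_cell_policy, "  alpha: ", x$alpha,
      "  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Read and write run configurations
#'
#' Flat YAML serialization of [run_config()]; category overrides are stored
#' as name -> member-PT lists.
#'
#' @param path Config file path.
#' @param config A `run_config` object.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cats <- if (is.null(y$categories)) builtin_categories() else
    lapply(names(y$categories), function(nm) adr_category(nm, unlist(y$categories[[nm]])))
  run_config(
    target_drugs = unlist(y$target_drugs),
    comparator_drugs = as.character(unlist(y$comparator_drugs) %||% character()),
    categories = cats,
    zero_cell_policy = y$zero_cell_policy %||% "haldane",
    alpha = y$alpha %||% 0.05,
    seed = y$seed %||% 1L
  )
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(
    target_drugs = as.list(config$target_drugs),
    comparator_drugs = as.list(config$comparator_drugs),
    categories = lapply(config$categories, `[[`, "members"),
    zero_cell_policy = config$zero_cell_policy,
    alpha = config$alpha,
    seed = config$seed
  ), path)
  invisible(path)
}
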