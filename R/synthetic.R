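#' Reporting profile of one drug in a synthetic spontaneous-report database
#'
#' @param drug Drug token.
#' @param n_cases Number of ICSRs to generate for the drug.
#' @param p_category Named numeric: per-category probability that a case for
#'   this drug reports at least one member PT (memberships are drawn
#'   independently per category).
#' @param pt_weights Named list, one element per category: named positive
#'   weights over that category's member PTs (the member reported when the
#'   case is in the category).
#' @param p_fatal_given_category Named numeric: probability of a fatal
#'   outcome given membership in each category. A case in several categories
#'   uses the maximum applicable probability.
#' @param p_fatal_background Fatal probability for cases in no category.
#' @param demographics List of four named probability vectors (`age_group`,
#'   `sex`, `origin`, `reporter`), each summing to 1 over (a subset of) the
#'   closed level sets.
#' @param co_suspect Optional second drug token; with probability
#'   `co_suspect_rate` a case names both drugs as suspected.
#' @param co_suspect_rate Probability in `[0, 1]`; default 0.
#' @return An object of class `drug_profile`.
#' @export
drug_profile <- function(drug, n_cases, p_category, pt_weights,
                         p_fatal_given_category, p_fatal_background,
                         demographics, co_suspect = NULL,
                         co_suspect_rate = 0) {
  stopifnot(is.character(drug), length(drug) == 1L, n_cases >= 0,
            all(p_category >= 0 & p_category <= 1),
            all(p_fatal_given_category >= 0 & p_fatal_given_category <= 1),
            p_fatal_background >= 0, p_fatal_background <= 1,
            co_suspect_rate >= 0, co_suspect_rate <= 1)
  if (!setequal(names(p_category), names(pt_weights)) ||
      !setequal(names(p_category), names(p_fatal_given_category))) {
    stop("p_category, pt_weights and p_fatal_given_category must share names",
         call. = FALSE)
  }
  for (w in pt_weights) {
    if (length(w) == 0L || any(w <= 0) || is.null(names(w))) {
      stop("pt_weights must be named positive vectors", call. = FALSE)
    }
  }
  for (v in c("age_group", "sex", "origin", "reporter")) {
    d <- demographics[[v]]
    if (is.null(d) || abs(sum(d) - 1) > 1e-8 || any(d < 0) ||
        !all(names(d) %in% icsr_levels_for(v))) {
      stop("demographics$", v, " must be a probability vector over the ",
           v, " levels", call. = FALSE)
    }
  }
  structure(list(
    drug = drug, n_cases = as.integer(n_cases), p_category = p_category,
    pt_weights = pt_weights, p_fatal_given_category = p_fatal_given_category,
    p_fatal_background = p_fatal_background, demographics = demographics,
    co_suspect = co_suspect, co_suspect_rate = co_suspect_rate
  ), class = "drug_profile")
}

#' Scenario: a whole synthetic spontaneous-report database
#'
#' @param profiles List of [drug_profile()] objects.
#' @param categories List of [adr_category()] objects the profiles'
#'   `p_category` names refer to; default the built-in DR/DI sets.
#' @param background_vocab Character vector of non-category PTs used as
#'   filler reactions; must be disjoint from every category member set.
#' @param seed Integer master seed; each profile draws from its own
#'   sub-stream derived from it, so adding a profile never perturbs the
#'   others' cases.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(profiles, categories = builtin_categories(),
                            background_vocab = default_background_vocab(),
                            seed = 1L) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "drug_profile")))
  names(categories) <- vapply(categories, `[[`, character(1), "name")
  members <- unlist(lapply(categories, `[[`, "members"), use.names = FALSE)
  clash <- intersect(pt_canonical(background_vocab), members)
  if (length(clash) > 0L) {
    stop("background_vocab overlaps category members: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  for (p in profiles) {
    bad <- setdiff(names(p$p_category), names(categories))
    if (length(bad) > 0L) {
      stop("profile '", p$drug, "' references unknown categories: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (nm in names(p$pt_weights)) {
      extra <- setdiff(pt_canonical(names(p$pt_weights[[nm]])),
                       categories[[nm]]$members)
      if (length(extra) > 0L) {
        stop("profile '", p$drug, "' weights non-member PTs in ", nm, ": ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(list(profiles = profiles, categories = categories,
                 background_vocab = background_vocab, seed = as.integer(seed)),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @export
default_background_vocab <- function() {
  c("Nausea", "Vomiting", "Diarrhoea", "Rash", "Pyrexia", "Headache",
    "Dizziness", "Pruritus", "Acute kidney injury", "Thrombocytopenia",
    "Anaemia", "Hepatotoxicity", "Seizure", "Hypotension", "Dyspnoea")
}

# Sub-stream seed for one profile: a small polynomial hash of the drug token
# folded into the master seed, kept inside the 32-bit signed range so it is a
# valid set.seed() argument. Stable across profile insertion order.
fork_seed <- function(seed, drug) {
  h <- 0
  for (code in utf8ToInt(drug_normalize(drug))) {
    h <- (h * 31 + code) %% 1048573
  }
  as.integer((abs(as.numeric(seed)) %% 1048573) * 1021 + h) %% 2147483647L
}

generate_profile_cases <- function(profile, scenario) {
  n <- profile$n_cases
  if (n == 0L) {
    return(icsr_dataset(character(), list(), list(), character(), character(),
                        character(), character(), logical()))
  }
  set.seed(fork_seed(scenario$seed, profile$drug))
  cat_names <- names(profile$p_category)

  # independent Bernoulli membership per category
  membership <- vapply(cat_names, function(nm)
    stats::runif(n) < profile$p_category[[nm]], logical(n))
  membership <- matrix(membership, nrow = n,
                       dimnames = list(NULL, cat_names))

  # long (case, pt) pairs: one weighted member PT per category membership,
  # plus 1-3 background PTs always
  idx <- integer(0); pts <- character(0)
  for (nm in cat_names) {
    hit <- which(membership[, nm])
    if (length(hit) > 0L) {
      w <- profile$pt_weights[[nm]]
      idx <- c(idx, hit)
      pts <- c(pts, sample(names(w), length(hit), replace = TRUE,
                           prob = w / sum(w)))
    }
  }
  k_bg <- sample(1:3, n, replace = TRUE)
  idx <- c(idx, rep.int(seq_len(n), k_bg))
  pts <- c(pts, sample(scenario$background_vocab, sum(k_bg), replace = TRUE))
  reactions <- unname(split(pts, factor(idx, levels = seq_len(n))))

  # fatal outcome: max applicable conditional probability, else background
  p_fatal <- rep(profile$p_fatal_background, n)
  for (nm in cat_names) {
    p_fatal <- pmax(p_fatal,
                    ifelse(membership[, nm], profile$p_fatal_given_category[[nm]], 0))
  }
  fatal <- stats::runif(n) < p_fatal

  draw <- function(d) sample(names(d), n, replace = TRUE, prob = d)
  drugs <- rep(list(profile$drug), n)
  if (!is.null(profile$co_suspect) && profile$co_suspect_rate > 0) {
    co <- stats::runif(n) < profile$co_suspect_rate
    drugs[co] <- lapply(drugs[co], c, profile$co_suspect)
  }
  # reactions from split() may repeat a background PT within a case; set
  # semantics are restored cheaply here instead of via icsr_dataset()
  dup <- vapply(reactions, anyDuplicated, integer(1)) > 0L
  reactions[dup] <- lapply(reactions[dup], unique)
  new_icsr_tbl(
    case_id   = sprintf("%s-%07d", gsub("[^A-Za-z0-9]+", "", profile$drug), seq_len(n)),
    drugs     = drugs,
    reactions = reactions,
    age_group = draw(profile$demographics$age_group),
    sex       = draw(profile$demographics$sex),
    origin    = draw(profile$demographics$origin),
    reporter  = draw(profile$demographics$reporter),
    fatal     = fatal
  )
}

#' Generate a synthetic ICSR dataset
#'
#' Draws, for every profile in the scenario, `n_cases` ICSRs: category
#' memberships Bernoulli(`p_category`) independently per category, one
#' weighted member PT per membership, one to three background PTs always,
#' demographics and the fatal flag per the profile. Fully determined by the
#' scenario seed.
#'
#' @param scenario A [scenario_config()].
#' @return An ICSR dataset with the profiles' cases stacked in profile order.
#' @export
generate_cases <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  parts <- lapply(scenario$profiles, generate_profile_cases, scenario = scenario)
  out <- dplyr::bind_rows(parts)
  class(out) <- c("icsr_tbl", class(out))
  out
}
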