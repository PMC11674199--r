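#' Assign a Brighton-style level of certainty to one case
#'
#' The level-1 (most specific), level-2 and level-3 predicates are
#' evaluated in order under three-valued logic; the assigned level is the
#' first that evaluates true. If none is true the case is either level 5
#' ("not a case") when the level-3 predicate -- the most sensitive
#' definition -- is definitively false, or level 4 ("insufficient
#' information") when it is undetermined. For level-4 results the
#' blocking unknowns are the unknown criteria contributing to the
#' undetermined evaluation of the level-3 predicate (the level whose
#' confirmation is blocked); for level-5 results the failed criteria are
#' the known criterion values that force the level-3 predicate false.
#'
#' @param case a `case_record` (its condition must match `rules`).
#' @param rules the condition's `rule_set`.
#' @return a `loc_result`: list with `level` (1-5), `satisfied_level`
#'   (1-3 or `NA`), `blocking_unknowns` (non-empty iff level 4) and
#'   `failed_criteria` (non-empty iff level 5).
#' @export
classify_case <- function(case, rules) {
  stopifnot(inherits(case, "case_record"), inherits(rules, "rule_set"))
  if (case$condition != rules$condition) {
    stop(sprintf("condition mismatch: case %s vs rule set %s",
                 case$condition, rules$condition), call. = FALSE)
  }
  ids <- rule_set_ids(rules)
  extra <- setdiff(names(case$criteria), ids)
  if (length(extra)) {
    stop(sprintf("case %s: criteria not in the %s rule set: %s",
                 case$case_id, rules$condition,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  av <- rep(NA, length(ids))
  names(av) <- ids
  known <- names(case$criteria)
  av[known] <- tri_to_logical(case$criteria[known])

  evals <- vapply(1:3, function(k) {
    eval_expr_lgl(rules[[paste0("level", k)]], av)
  }, logical(1))
  satisfied <- which(evals)[1]      # which() drops NA and FALSE
  if (!is.na(satisfied)) {
    lvl <- as.integer(satisfied)
    return(new_loc_result(lvl, satisfied_level = lvl))
  }
  if (isFALSE(evals[3])) {
    new_loc_result(5L, failed_criteria =
                     deciding_atoms(rules$level3, av, FALSE))
  } else {
    new_loc_result(4L, blocking_unknowns =
                     unknown_contributors(rules$level3, av))
  }
}

new_loc_result <- function(level, satisfied_level = NA_integer_,
                           blocking_unknowns = character(),
                           failed_criteria = character()) {
  structure(list(level = level,
                 satisfied_level = as.integer(satisfied_level),
                 blocking_unknowns = blocking_unknowns,
                 failed_criteria = failed_criteria),
            class = "loc_result")
}

#' @export
print.loc_result <- function(x, ...) {
  cat(sprintf("<loc_result> level %d", x$level))
  if (!is.na(x$satisfied_level)) {
    cat(sprintf(" (satisfied level-%d predicate)", x$satisfied_level))
  }
  cat("\n")
  if (length(x$blocking_unknowns)) {
    cat("  blocking unknowns:", paste(x$blocking_unknowns, collapse = ", "),
        "\n")
  }
  if (length(x$failed_criteria)) {
    cat("  failed criteria:", paste(x$failed_criteria, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Explain why a case is non-classifiable (level 4)
#'
#' Returns the blocking unknown criteria of a level-4 case: resolving
#' every one of them to a known value forces the classification into
#' levels 1-3 or 5.
#'
#' @inheritParams classify_case
#' @return character vector of criterion ids.
#' @export
explain_level4 <- function(case, rules) {
  res <- classify_case(case, rules)
  if (res$level != 4L) {
    stop(sprintf("case %s is level %d, not level 4", case$case_id,
                 res$level), call. = FALSE)
  }
  res$blocking_unknowns
}

#' Classify every case of a roster
#'
#' @param roster a roster data frame (see [read_linelist()]).
#' @param rules named list of `rule_set`s keyed by condition code;
#'   defaults to the shipped definitions. Every condition occurring in
#'   the roster must have a rule set.
#' @return the roster with appended columns `loc`, `satisfied_level`,
#'   `blocking_unknowns` and `failed_criteria` (the latter two
#'   semicolon-joined id lists).
#' @export
classify_roster <- function(roster, rules = load_rule_sets()) {
  records <- roster_to_records(roster)
  missing_rules <- setdiff(unique(roster$condition), names(rules))
  if (length(missing_rules)) {
    stop("no rule set for condition(s): ",
         paste(missing_rules, collapse = ", "), call. = FALSE)
  }
  results <- lapply(records, function(r) {
    rs <- rules[[r$condition]]
    # a record may carry crit.* columns belonging to other conditions in
    # the same line-list; restrict to this condition's criteria
    r$criteria <- r$criteria[intersect(names(r$criteria), rule_set_ids(rs))]
    classify_case(r, rs)
  })
  roster$loc <- vapply(results, `[[`, integer(1), "level")
  roster$satisfied_level <- vapply(results, `[[`, integer(1),
                                   "satisfied_level")
  roster$blocking_unknowns <- vapply(results, function(x) {
    paste(x$blocking_unknowns, collapse = ";")
  }, character(1))
  roster$failed_criteria <- vapply(results, function(x) {
    paste(x$failed_criteria, collapse = ";")
  }, character(1))
  roster
}
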