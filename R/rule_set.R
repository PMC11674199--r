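#' Condition codes
#'
#' Closed vocabulary of the adverse events of special interest (AESI)
#' covered by the surveillance. Encephalitis and myelitis are distinct
#' codes (a dual-diagnosed patient appears as two case records).
#'
#' @return character vector of condition codes.
#' @export
condition_codes <- function() {
  c("MYOCARDITIS", "PERICARDITIS", "INJECTION_SITE_ABSCESS", "TTS",
    "THROMBOCYTOPENIA", "THROMBOSIS_THROMBOEMBOLISM", "ANAPHYLAXIS",
    "ADEM", "BELLS_PALSY", "GENERALIZED_CONVULSION", "GBS_FISHER",
    "ENCEPHALITIS", "MYELITIS")
}

criterion_categories <- function() {
  c("CLINICAL", "TEMPORAL", "LABORATORY", "ELECTROPHYSIOLOGY",
    "IMAGING", "EXCLUSION")
}

#' Define one case-definition criterion
#'
#' @param id short unique token (used as atom id in predicates and as the
#'   `crit.<id>` line-list column suffix).
#' @param label human-readable criterion text.
#' @param category one of CLINICAL, TEMPORAL, LABORATORY,
#'   ELECTROPHYSIOLOGY, IMAGING, EXCLUSION; drives grouping in
#'   criterion-prevalence tables.
#' @return a `criterion_def` object.
#' @export
criterion_def <- function(id, label = id, category = "CLINICAL") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  category <- match.arg(toupper(category), criterion_categories())
  structure(list(id = id, label = label, category = category),
            class = "criterion_def")
}

#' Construct a rule set (machine form of one case definition)
#'
#' A rule set pairs a condition's criteria with the three level
#' predicates: level 1 (highest specificity), level 2 (intermediate) and
#' level 3 (lowest specificity / highest sensitivity). Under fully-known
#' criterion assignments the predicates must nest, level 1 => level 2 =>
#' level 3; [validate_rule_set()] checks this exhaustively.
#'
#' @param condition one of [condition_codes()].
#' @param criteria list of [criterion_def()]s.
#' @param level1,level2,level3 `rule_expr` predicates over the criteria.
#' @param version free-text version label (kept in audit logs).
#' @return a `rule_set` object.
#' @export
rule_set <- function(condition, criteria, level1, level2, level3,
                     version = "unversioned") {
  condition <- match.arg(condition, condition_codes())
  criteria <- lapply(criteria, function(cr) {
    if (inherits(cr, "criterion_def")) cr else do.call(criterion_def, cr)
  })
  ids <- vapply(criteria, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate criterion ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  levels <- list(level1 = as_expr(level1), level2 = as_expr(level2),
                 level3 = as_expr(level3))
  for (nm in names(levels)) {
    dangling <- setdiff(expr_atoms(levels[[nm]]), ids)
    if (length(dangling)) {
      stop(sprintf("%s references undeclared criterion id(s): %s",
                   nm, paste(dangling, collapse = ", ")), call. = FALSE)
    }
  }
  structure(c(list(condition = condition, criteria = criteria,
                   version = version), levels),
            class = "rule_set")
}

rule_set_ids <- function(rules) {
  vapply(rules$criteria, `[[`, "", "id")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %s (version %s)\n", x$condition, x$version))
  cat(sprintf("  criteria (%d): %s\n", length(x$criteria),
              paste(rule_set_ids(x), collapse = ", ")))
  for (lv in 1:3) {
    cat(sprintf("  level %d: %s\n", lv, format(x[[paste0("level", lv)]])))
  }
  invisible(x)
}

#' Load a rule set from a JSON file
#'
#' The on-disk form is one JSON document per condition with keys
#' `condition`, `version`, `criteria` (array of `{id, label, category}`)
#' and `levels` (object with keys `"1"`, `"2"`, `"3"`, each a nested-array
#' expression such as `["ALL", "c1", ["ANY", "l1", "l2"]]`; atoms are bare
#' strings, thresholds `["AT_LEAST", k, ...]`, negation `["NOT", x]`).
#' Schema violations are reported with JSON-pointer-style paths.
#'
#' @param path path to a `.json` rule-set file.
#' @return a validated `rule_set`.
#' @seealso [default_rules_dir()] for the shipped definitions.
#' @export
load_rule_set <- function(path) {
  if (!file.exists(path)) stop("no such rule-set file: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("%s: not valid JSON (%s)", path,
                                     conditionMessage(e)), call. = FALSE))
  need <- function(key) {
    if (is.null(doc[[key]])) {
      stop(sprintf("%s: missing required key /%s", path, key), call. = FALSE)
    }
    doc[[key]]
  }
  condition <- need("condition")
  if (!is.character(condition) || !condition %in% condition_codes()) {
    stop(sprintf("%s: /condition: unknown condition code '%s'", path,
                 paste(condition, collapse = "")), call. = FALSE)
  }
  crit_raw <- need("criteria")
  if (!is.list(crit_raw) || length(crit_raw) == 0L) {
    stop(path, ": /criteria: expected non-empty array", call. = FALSE)
  }
  criteria <- lapply(seq_along(crit_raw), function(i) {
    cr <- crit_raw[[i]]
    if (is.null(cr$id)) {
      stop(sprintf("%s: /criteria/%d: missing id", path, i - 1L),
           call. = FALSE)
    }
    criterion_def(cr$id, cr$label %||% cr$id, cr$category %||% "CLINICAL")
  })
  lv_raw <- need("levels")
  levels <- lapply(c("1", "2", "3"), function(k) {
    if (is.null(lv_raw[[k]])) {
      stop(sprintf("%s: /levels/%s: missing predicate", path, k),
           call. = FALSE)
    }
    expr_from_json(lv_raw[[k]], where = sprintf("%s: /levels/%s", path, k))
  })
  tryCatch(
    rule_set(condition, criteria, levels[[1]], levels[[2]], levels[[3]],
             version = doc$version %||% "unversioned"),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                             call. = FALSE))
}

#' Write a rule set to its JSON file form
#'
#' @param rules a `rule_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rule_set <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  doc <- list(
    condition = rules$condition,
    version = rules$version,
    criteria = lapply(rules$criteria, function(cr) {
      list(id = cr$id, label = cr$label, category = cr$category)
    }),
    levels = list(
      "1" = expr_to_json(rules$level1),
      "2" = expr_to_json(rules$level2),
      "3" = expr_to_json(rules$level3)
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate the level-nesting invariant of a rule set
#'
#' Exhaustively enumerates all fully-known assignments over the rule set's
#' atoms (2^n, refused for n > 20) and verifies that any assignment
#' satisfying level 1 also satisfies level 2, and any satisfying level 2
#' also satisfies level 3 -- i.e. specificity strictly tightens with the
#' level. The first counterexample assignment, if any, is reported.
#'
#' @param rules a `rule_set`.
#' @return a list with elements `ok` (logical), `n_assignments` checked,
#'   and `counterexample` (`NULL`, or a named tri-state vector plus the
#'   violated implication).
#' @export
validate_rule_set <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  ids <- unique(unlist(lapply(rules[c("level1", "level2", "level3")],
                              expr_atoms), use.names = FALSE))
  n <- length(ids)
  if (n > 20L) {
    stop(sprintf("refusing exhaustive check over %d atoms (limit 20)", n),
         call. = FALSE)
  }
  counter <- NULL
  for (mask in 0:(2^n - 1)) {
    av <- as.logical(bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L))
    names(av) <- ids
    v1 <- eval_expr_lgl(rules$level1, av)
    v2 <- eval_expr_lgl(rules$level2, av)
    v3 <- eval_expr_lgl(rules$level3, av)
    broken <- if (isTRUE(v1) && !isTRUE(v2)) "level1 => level2"
              else if (isTRUE(v2) && !isTRUE(v3)) "level2 => level3"
              else NULL
    if (!is.null(broken)) {
      tri <- ifelse(av, "present", "absent")
      names(tri) <- ids
      counter <- list(implication = broken, assignment = tri)
      break
    }
  }
  list(ok = is.null(counter), n_assignments = 2^n, counterexample = counter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
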