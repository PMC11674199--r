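#' Rule expressions
#'
#' Case-definition predicates are small expression trees over criterion
#' atoms. Node kinds: `atom(id)`, `all_of(...)` (conjunction),
#' `any_of(...)` (disjunction), `at_least(k, ...)` (threshold) and
#' `not_of(x)` (negation). Expressions are evaluated under strong Kleene
#' three-valued logic against a tri-state criterion assignment, so a
#' predicate can come out true, false, or undetermined ("unknown").
#'
#' @param id criterion id (single string).
#' @param ... child expressions (or, for convenience, bare criterion id
#'   strings, which are wrapped in `atom()`).
#' @param k threshold for `at_least`; must satisfy `1 <= k <=` number of
#'   children.
#' @param x child expression for `not_of`.
#' @return an object of class `rule_expr`.
#' @examples
#' e <- all_of("a", any_of("b", "c"))
#' eval_expr(e, c(a = "present", b = "unknown", c = "absent"))
#' @name rule_expr
NULL

new_expr <- function(.kind, ...) {
  structure(list(kind = .kind, ...), class = "rule_expr")
}

as_expr <- function(x) {
  if (inherits(x, "rule_expr")) return(x)
  if (is.character(x) && length(x) == 1L) return(atom(x))
  stop("not a rule expression: ", deparse(x), call. = FALSE)
}

#' @rdname rule_expr
#' @export
atom <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  new_expr("atom", id = id)
}

#' @rdname rule_expr
#' @export
all_of <- function(...) {
  args <- lapply(list(...), as_expr)
  stopifnot(length(args) >= 1L)
  new_expr("all", args = args)
}

#' @rdname rule_expr
#' @export
any_of <- function(...) {
  args <- lapply(list(...), as_expr)
  stopifnot(length(args) >= 1L)
  new_expr("any", args = args)
}

#' @rdname rule_expr
#' @export
at_least <- function(k, ...) {
  raw <- list(...)
  if (length(raw) == 1L && is.list(raw[[1L]]) &&
      !inherits(raw[[1L]], "rule_expr")) {
    raw <- raw[[1L]]
  }
  args <- lapply(raw, as_expr)
  k <- as.integer(k)
  if (!(k >= 1L && k <= length(args))) {
    stop(sprintf("at_least: k = %d outside 1..%d", k, length(args)),
         call. = FALSE)
  }
  new_expr("at_least", k = k, args = args)
}

#' @rdname rule_expr
#' @export
not_of <- function(x) {
  new_expr("not", arg = as_expr(x))
}

#' Criterion ids referenced by an expression
#'
#' @param expr a `rule_expr`.
#' @return character vector of distinct atom ids, in first-occurrence order.
#' @export
expr_atoms <- function(expr) {
  stopifnot(inherits(expr, "rule_expr"))
  walk <- function(e) {
    switch(e$kind,
      atom = e$id,
      not = walk(e$arg),
      unlist(lapply(e$args, walk), use.names = FALSE)
    )
  }
  unique(walk(expr))
}

#' Evaluate a rule expression under three-valued logic
#'
#' Strong Kleene semantics: conjunction is false if any child is false,
#' true if all are true, otherwise unknown; disjunction dually;
#' `at_least(k, ...)` is true when at least `k` children are true, false
#' when even resolving every unknown child in favour could not reach `k`,
#' and unknown otherwise; negation maps unknown to unknown. Criterion ids
#' absent from `assignment` read as `"unknown"`.
#'
#' @param expr a `rule_expr`.
#' @param assignment named character vector (or list) of tri-state values,
#'   names are criterion ids.
#' @return `TRUE`, `FALSE`, or `NA` (unknown).
#' @export
eval_expr <- function(expr, assignment) {
  av <- assignment_logical(expr, assignment)
  eval_expr_lgl(expr, av)
}

# named logical vector over all atoms of expr; missing ids -> NA
assignment_logical <- function(expr, assignment) {
  assignment <- unlist(assignment)
  if (length(assignment)) assert_tri(assignment, "assignment")
  ids <- expr_atoms(expr)
  av <- rep(NA, length(ids))
  names(av) <- ids
  hit <- intersect(ids, names(assignment))
  av[hit] <- tri_to_logical(assignment[hit])
  av
}

eval_expr_lgl <- function(e, av) {
  switch(e$kind,
    atom = unname(av[[e$id]]),
    not = !eval_expr_lgl(e$arg, av),
    all = {
      vals <- vapply(e$args, eval_expr_lgl, logical(1), av = av)
      all(vals)           # base logical all(): strong-Kleene conjunction
    },
    any = {
      vals <- vapply(e$args, eval_expr_lgl, logical(1), av = av)
      any(vals)
    },
    at_least = {
      vals <- vapply(e$args, eval_expr_lgl, logical(1), av = av)
      n_true <- sum(vals, na.rm = TRUE)
      n_unk <- sum(is.na(vals))
      if (n_true >= e$k) TRUE
      else if (n_true + n_unk < e$k) FALSE
      else NA
    },
    stop("unknown expression kind: ", e$kind)
  )
}

# Atoms with unknown values that contribute to an UNKNOWN evaluation.
# Precondition: eval_expr_lgl(e, av) is NA.
unknown_contributors <- function(e, av) {
  switch(e$kind,
    atom = if (is.na(av[[e$id]])) e$id else character(),
    not = unknown_contributors(e$arg, av),
    {
      vals <- vapply(e$args, eval_expr_lgl, logical(1), av = av)
      unique(unlist(lapply(e$args[is.na(vals)], unknown_contributors, av = av),
                    use.names = FALSE))
    }
  )
}

# Atoms with known values that force expr to evaluate to `target`
# (TRUE/FALSE). Precondition: eval_expr_lgl(e, av) == target.
deciding_atoms <- function(e, av, target) {
  switch(e$kind,
    atom = {
      v <- av[[e$id]]
      if (!is.na(v) && v == target) e$id else character()
    },
    not = deciding_atoms(e$arg, av, !target),
    all = ,
    any = ,
    at_least = {
      vals <- vapply(e$args, eval_expr_lgl, logical(1), av = av)
      pick <- if (e$kind == "all" && target) {
        rep(TRUE, length(vals))          # every child is true and needed
      } else if (e$kind == "any" && !target) {
        rep(TRUE, length(vals))          # every child is false and needed
      } else {
        !is.na(vals) & vals == target    # the children that realize target
      }
      unique(unlist(lapply(e$args[pick], deciding_atoms, av = av,
                           target = target), use.names = FALSE))
    }
  )
}

#' @export
format.rule_expr <- function(x, ...) {
  switch(x$kind,
    atom = x$id,
    not = paste0("NOT(", format(x$arg), ")"),
    all = paste0("ALL(", paste(vapply(x$args, format, ""), collapse = ", "), ")"),
    any = paste0("ANY(", paste(vapply(x$args, format, ""), collapse = ", "), ")"),
    at_least = paste0("AT_LEAST(", x$k, "; ",
                      paste(vapply(x$args, format, ""), collapse = ", "), ")")
  )
}

#' @export
print.rule_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# --- JSON (nested-array) serialization -------------------------------------
# ["ALL", "c1", ["ANY", "l1", "l2"]]; atoms are bare strings;
# ["AT_LEAST", 2, ...children]; ["NOT", child].

expr_from_json <- function(x, where = "levels") {
  if (is.character(x) && length(x) == 1L) return(atom(x))
  if (!is.list(x) || length(x) == 0L) {
    stop(sprintf("%s: expected operator array or atom string", where),
         call. = FALSE)
  }
  op <- x[[1L]]
  if (!is.character(op) || length(op) != 1L) {
    stop(sprintf("%s/0: operator must be a string", where), call. = FALSE)
  }
  kids <- function(from) lapply(seq(from, length.out = length(x) - from + 1L),
                                function(i) expr_from_json(x[[i]],
                                  where = paste0(where, "/", i - 1L)))
  switch(toupper(op),
    ALL = {
      if (length(x) < 2L) stop(where, ": ALL needs children", call. = FALSE)
      new_expr("all", args = kids(2L))
    },
    ANY = {
      if (length(x) < 2L) stop(where, ": ANY needs children", call. = FALSE)
      new_expr("any", args = kids(2L))
    },
    AT_LEAST = {
      if (length(x) < 3L || !is.numeric(x[[2L]])) {
        stop(where, ": AT_LEAST needs a count and children", call. = FALSE)
      }
      at_least(x[[2L]], kids(3L))
    },
    NOT = {
      if (length(x) != 2L) stop(where, ": NOT takes one child", call. = FALSE)
      new_expr("not", arg = expr_from_json(x[[2L]], paste0(where, "/1")))
    },
    stop(sprintf("%s/0: unknown operator '%s'", where, op), call. = FALSE)
  )
}

expr_to_json <- function(e) {
  switch(e$kind,
    atom = e$id,
    not = list("NOT", expr_to_json(e$arg)),
    all = c(list("ALL"), lapply(e$args, expr_to_json)),
    any = c(list("ANY"), lapply(e$args, expr_to_json)),
    at_least = c(list("AT_LEAST", e$k), lapply(e$args, expr_to_json))
  )
}
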