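# Independent brute-force oracle for the three-valued engine: classical
# two-valued evaluation of an expression tree over a complete logical
# assignment, written without reference to the package's evaluator.
eval2 <- function(e, bools) {
  if (e$kind == "atom") {
    v <- bools[[e$id]]
    stopifnot(!is.na(v))
    return(v)
  }
  if (e$kind == "not") return(!eval2(e$arg, bools))
  child <- sapply(e$args, eval2, bools = bools)
  if (e$kind == "all") return(sum(child) == length(child))
  if (e$kind == "any") return(sum(child) > 0)
  if (e$kind == "at_least") return(sum(child) >= e$k)
  stop("bad node")
}

# All two-valued completions of a tri-state assignment (list of named
# logical vectors).
completions <- function(assignment) {
  unk <- names(assignment)[assignment == "unknown"]
  base <- tri_to_logical(assignment)
  names(base) <- names(assignment)
  if (length(unk) == 0L) return(list(base))
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(unk)))
  lapply(seq_len(nrow(grid)), function(i) {
    b <- base
    b[unk] <- unlist(grid[i, ])
    b
  })
}

# Random expression over the given atom ids.
random_expr <- function(atoms, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(atom(sample(atoms, 1)))
  }
  kind <- sample(c("all", "any", "at_least", "not"), 1)
  if (kind == "not") return(not_of(random_expr(atoms, depth - 1)))
  n_kids <- sample(2:3, 1)
  kids <- lapply(seq_len(n_kids), function(i) random_expr(atoms, depth - 1))
  if (kind == "all") do.call(all_of, kids)
  else if (kind == "any") do.call(any_of, kids)
  else at_least(sample(n_kids, 1), kids)
}

# Random tri-state assignment over atom ids.
random_assignment <- function(atoms, p_unknown = 1 / 3) {
  stats::setNames(
    sample(tri_levels(), length(atoms), replace = TRUE,
           prob = c((1 - p_unknown) / 2, (1 - p_unknown) / 2, p_unknown)),
    atoms)
}

# Minimal fully-specified GBS case record used across tests.
gbs_case <- function(case_id = "G1", ...) {
  case_record(case_id, "GBS_FISHER", age = 30, sex = "FEMALE",
              residence = "ADDIS_ABABA", detection_site = "EOPD",
              criteria = c(...))
}

gbs_core_present <- function() {
  c(bilateral_weakness = "present", flaccid_weakness = "present",
    dtr_decreased_in_weak_limbs = "present",
    onset_nadir_12h_28d = "present", alt_dx_absent = "present")
}
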