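#' Case records and surveillance rosters
#'
#' A roster is a line-list: a data frame with one row per suspected AESI
#' case and fixed columns `case_id`, `condition`, `age` (integer years),
#' `sex` (`MALE`/`FEMALE`), `residence` (`ADDIS_ABABA`/`OUTSIDE`),
#' `detection_site` (`EOPD`/`IPD`), followed by one column per criterion
#' named `crit.<id>` holding tri-state values. Criteria a row does not
#' mention read as `"unknown"`. On disk (CSV) the tri-state cells use the
#' [tri_from_token()] vocabulary: `yes` / `no` / blank.
#'
#' @name roster
NULL

roster_fixed_cols <- function() {
  c("case_id", "condition", "age", "sex", "residence", "detection_site")
}

#' Construct a single case record
#'
#' @param case_id unique token.
#' @param condition one of [condition_codes()].
#' @param age integer age in years (>= 0).
#' @param sex `"MALE"` or `"FEMALE"`.
#' @param residence `"ADDIS_ABABA"` or `"OUTSIDE"`.
#' @param detection_site `"EOPD"` (emergency outpatient) or `"IPD"`
#'   (inpatient).
#' @param criteria named character vector of tri-state values, names are
#'   criterion ids.
#' @param onset_to_nadir_hours optional non-negative number (GBS
#'   convenience field): when given and the `onset_nadir_12h_28d`
#'   criterion is not set explicitly, it is derived as present iff the
#'   interval lies within 12 hours to 28 days.
#' @return a `case_record` (named list).
#' @export
case_record <- function(case_id, condition, age, sex, residence,
                        detection_site, criteria = character(),
                        onset_to_nadir_hours = NA_real_) {
  condition <- match.arg(condition, condition_codes())
  sex <- match.arg(sex, c("MALE", "FEMALE"))
  residence <- match.arg(residence, c("ADDIS_ABABA", "OUTSIDE"))
  detection_site <- match.arg(detection_site, c("EOPD", "IPD"))
  age <- as.integer(age)
  stopifnot(length(age) == 1L, !is.na(age), age >= 0L)
  criteria <- unlist(criteria)
  if (length(criteria)) {
    stopifnot(!is.null(names(criteria)), all(nzchar(names(criteria))))
    assert_tri(criteria, "criterion value")
  }
  if (!is.na(onset_to_nadir_hours)) {
    stopifnot(onset_to_nadir_hours >= 0)
    if (!"onset_nadir_12h_28d" %in% names(criteria)) {
      within <- onset_to_nadir_hours >= 12 && onset_to_nadir_hours <= 28 * 24
      criteria[["onset_nadir_12h_28d"]] <- if (within) "present" else "absent"
    }
  }
  structure(list(case_id = as.character(case_id), condition = condition,
                 age = age, sex = sex, residence = residence,
                 detection_site = detection_site, criteria = criteria),
            class = "case_record")
}

#' Look up a case's tri-state value for a criterion
#'
#' @param case a `case_record`.
#' @param id criterion id.
#' @return `"present"`, `"absent"` or `"unknown"` (the default for any
#'   criterion the record does not mention).
#' @export
case_criterion <- function(case, id) {
  if (id %in% names(case$criteria)) case$criteria[[id]] else "unknown"
}

#' Convert case records to a roster data frame
#'
#' @param records list of `case_record`s.
#' @return a roster data frame with tri-state `crit.*` columns.
#' @export
records_to_roster <- function(records) {
  stopifnot(length(records) > 0L)
  crit_ids <- unique(unlist(lapply(records, function(r) names(r$criteria)),
                            use.names = FALSE))
  rows <- lapply(records, function(r) {
    crit <- rep("unknown", length(crit_ids))
    names(crit) <- crit_ids
    crit[names(r$criteria)] <- r$criteria
    c(list(case_id = r$case_id, condition = r$condition, age = r$age,
           sex = r$sex, residence = r$residence,
           detection_site = r$detection_site),
      as.list(crit))
  })
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  names(df) <- c(roster_fixed_cols(), paste0("crit.", crit_ids))
  rownames(df) <- NULL
  validate_roster(df)
}

#' Convert a roster data frame to case records
#'
#' @param roster a roster data frame.
#' @return list of `case_record`s.
#' @export
roster_to_records <- function(roster) {
  roster <- validate_roster(roster)
  crit_cols <- grep("^crit\\.", names(roster), value = TRUE)
  ids <- sub("^crit\\.", "", crit_cols)
  lapply(seq_len(nrow(roster)), function(i) {
    crit <- as.character(roster[i, crit_cols])
    names(crit) <- ids
    crit <- crit[crit != "unknown"]   # unmentioned criteria read as unknown
    case_record(roster$case_id[i], roster$condition[i], roster$age[i],
                roster$sex[i], roster$residence[i],
                roster$detection_site[i], criteria = crit)
  })
}

validate_roster <- function(roster, file = NULL) {
  src <- if (is.null(file)) "roster" else file
  missing_cols <- setdiff(roster_fixed_cols(), names(roster))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", src,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(roster) == 0L) stop(src, ": empty roster", call. = FALSE)
  bad_cond <- which(!roster$condition %in% condition_codes())
  if (length(bad_cond)) {
    stop(sprintf("%s: row %d: unknown condition code '%s'", src,
                 bad_cond[1], roster$condition[bad_cond[1]]), call. = FALSE)
  }
  roster$age <- as.integer(roster$age)
  if (anyNA(roster$age) || any(roster$age < 0L)) {
    stop(src, ": age must be a non-negative integer", call. = FALSE)
  }
  check_enum <- function(col, allowed) {
    bad <- which(!roster[[col]] %in% allowed)
    if (length(bad)) {
      stop(sprintf("%s: row %d: invalid %s '%s'", src, bad[1], col,
                   roster[[col]][bad[1]]), call. = FALSE)
    }
  }
  check_enum("sex", c("MALE", "FEMALE"))
  check_enum("residence", c("ADDIS_ABABA", "OUTSIDE"))
  check_enum("detection_site", c("EOPD", "IPD"))
  if (anyDuplicated(roster$case_id)) {
    stop(src, ": duplicate case_id", call. = FALSE)
  }
  for (col in grep("^crit\\.", names(roster), value = TRUE)) {
    assert_tri(roster[[col]], paste0("value in column ", col))
  }
  roster
}

#' Read a line-list CSV into a roster
#'
#' @param path CSV file path (UTF-8, header row; `crit.*` cells use the
#'   yes/no/blank vocabulary of [tri_from_token()]).
#' @return a validated roster data frame.
#' @export
read_linelist <- function(path) {
  if (!file.exists(path)) stop("no such line-list: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop(path, ": empty roster", call. = FALSE)
  for (col in grep("^crit\\.", names(df), value = TRUE)) {
    df[[col]] <- vapply(seq_len(nrow(df)), function(i) {
      tri_from_token(df[[col]][i],
                     context = sprintf("%s row %d column %s", path, i, col))
    }, character(1))
  }
  if ("age" %in% names(df)) df$age <- as.integer(df$age)
  validate_roster(df, file = path)
}

#' Write a roster to a line-list CSV
#'
#' Inverse of [read_linelist()]: tri-state columns are serialized as
#' `yes` / `no` / blank, so a written roster re-parses identically.
#'
#' @param roster a roster data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_linelist <- function(roster, path) {
  roster <- validate_roster(roster)
  out <- roster
  for (col in grep("^crit\\.", names(out), value = TRUE)) {
    out[[col]] <- unname(tri_to_token(out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
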