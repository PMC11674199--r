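#' Integer percentages, round half up
#'
#' The reporting convention throughout the package: percentages are
#' rounded half up to integer percent (7/8 prints as 88). An undefined
#' percentage (denominator 0) is `NA` and renders as an em-dash, never 0.
#'
#' @param n numerator count(s).
#' @param total denominator count(s).
#' @return integer vector (NA where `total` is 0).
#' @export
pct_int <- function(n, total) {
  out <- ifelse(total > 0, floor(100 * n / total + 0.5), NA_real_)
  as.integer(out)
}

fmt_pct <- function(p) ifelse(is.na(p), "—", as.character(p))

fmt_n_pct <- function(n, total) {
  sprintf("%d/%d (%s)", n, total, fmt_pct(pct_int(n, total)))
}

# round-half-up integer median (even-sized groups: mean of central pair)
median_int <- function(x) as.integer(floor(stats::median(x) + 0.5))

require_classified <- function(roster) {
  if (!"loc" %in% names(roster)) {
    stop("roster has no 'loc' column; run classify_roster() first",
         call. = FALSE)
  }
  if (nrow(roster) == 0L) stop("empty roster", call. = FALSE)
  stopifnot(all(roster$loc %in% 1:5))
  roster
}

#' Level-of-certainty distribution
#'
#' Counts and integer percentages of cases at each level 1-5, per
#' condition and overall, plus the combined "confirmed" (levels 1-3) and
#' "classifiable" (levels 1-3 or 5, i.e. not level 4) groupings.
#'
#' @param classified a classified roster (output of [classify_roster()]).
#' @return a `loc_distribution`: data frame with one row per condition
#'   plus a `TOTAL` row; columns `condition`, `n`, `l1`..`l5`,
#'   `confirmed_n`, `confirmed_pct`, `classifiable_n`,
#'   `classifiable_pct`, and per-level percentage columns `l1_pct` ..
#'   `l5_pct`.
#' @export
summarize_loc <- function(classified) {
  classified <- require_classified(classified)
  one <- function(sub, label) {
    n <- nrow(sub)
    lv <- vapply(1:5, function(k) sum(sub$loc == k), integer(1))
    conf <- sum(lv[1:3])
    clas <- conf + lv[5]
    out <- data.frame(condition = label, n = n, l1 = lv[1], l2 = lv[2],
                      l3 = lv[3], l4 = lv[4], l5 = lv[5],
                      confirmed_n = conf, confirmed_pct = pct_int(conf, n),
                      classifiable_n = clas,
                      classifiable_pct = pct_int(clas, n),
                      stringsAsFactors = FALSE)
    for (k in 1:5) out[[paste0("l", k, "_pct")]] <- pct_int(lv[k], n)
    out
  }
  conds <- sort(unique(classified$condition))
  rows <- lapply(conds, function(cc) {
    one(classified[classified$condition == cc, , drop = FALSE], cc)
  })
  out <- rbind(do.call(rbind, rows), one(classified, "TOTAL"))
  rownames(out) <- NULL
  class(out) <- c("loc_distribution", class(out))
  out
}

#' Tabulate reasons for level-4 (non-classifiable) cases
#'
#' @param classified a classified roster.
#' @return named list, one entry per condition with level-4 cases:
#'   `count` and `reasons`, the multiset (with repeats across cases) of
#'   blocking criterion ids. Empty list if the roster has no level-4
#'   case.
#' @export
tabulate_level4_reasons <- function(classified) {
  classified <- require_classified(classified)
  lv4 <- classified[classified$loc == 4L, , drop = FALSE]
  if (nrow(lv4) == 0L) return(stats::setNames(list(), character()))
  out <- lapply(split(lv4, lv4$condition), function(sub) {
    list(count = nrow(sub),
         reasons = unlist(strsplit(sub$blocking_unknowns, ";"),
                          use.names = FALSE))
  })
  out[order(names(out))]
}

#' Criterion-prevalence table for one condition
#'
#' For each criterion of the condition's rule set: `n`, the number of
#' cases with the criterion present, over `N`, the number of cases with
#' a known (non-missing) value, with the integer percentage -- the
#' "n/N (%)" convention of criterion-availability tables.
#'
#' @param roster a roster data frame (classification columns not
#'   required).
#' @param condition condition code; must occur in the roster.
#' @param rules the condition's `rule_set` (defaults to the shipped
#'   definition).
#' @return a `criterion_prevalence` data frame with columns `category`,
#'   `id`, `label`, `n`, `N`, `percent`, `display`.
#' @export
criterion_prevalence <- function(roster, condition,
                                 rules = load_rule_sets()[[condition]]) {
  condition <- match.arg(condition, condition_codes())
  stopifnot(inherits(rules, "rule_set"), rules$condition == condition)
  sub <- roster[roster$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no cases of condition ", condition, " in roster", call. = FALSE)
  }
  rows <- lapply(rules$criteria, function(cr) {
    col <- paste0("crit.", cr$id)
    vals <- if (col %in% names(sub)) sub[[col]] else rep("unknown", nrow(sub))
    n <- sum(vals == "present")
    N <- sum(vals != "unknown")
    data.frame(category = cr$category, id = cr$id, label = cr$label,
               n = n, N = N, percent = pct_int(n, N),
               display = fmt_n_pct(n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("criterion_prevalence", class(out))
  out
}

#' Demographics table
#'
#' One row per condition plus a `TOTAL` row: cases detected at the
#' emergency outpatient department (EOPD) and inpatient department (IPD)
#' with column percentages, total cases with percentage of all cases,
#' median age with range, and male and Addis Ababa residence counts with
#' row percentages.
#'
#' @param roster a roster data frame.
#' @return a `demographics_table` data frame.
#' @export
demographics_table <- function(roster) {
  roster <- validate_roster(roster)
  tot_eopd <- sum(roster$detection_site == "EOPD")
  tot_ipd <- sum(roster$detection_site == "IPD")
  tot <- nrow(roster)
  one <- function(sub, label) {
    eopd <- sum(sub$detection_site == "EOPD")
    ipd <- sum(sub$detection_site == "IPD")
    n <- nrow(sub)
    data.frame(
      condition = label,
      eopd_n = eopd, eopd_pct = pct_int(eopd, tot_eopd),
      ipd_n = ipd, ipd_pct = pct_int(ipd, tot_ipd),
      total_n = n, total_pct = pct_int(n, tot),
      age_median = median_int(sub$age),
      age_min = min(sub$age), age_max = max(sub$age),
      male_n = sum(sub$sex == "MALE"),
      male_pct = pct_int(sum(sub$sex == "MALE"), n),
      addis_n = sum(sub$residence == "ADDIS_ABABA"),
      addis_pct = pct_int(sum(sub$residence == "ADDIS_ABABA"), n),
      stringsAsFactors = FALSE)
  }
  conds <- sort(unique(roster$condition))
  rows <- lapply(conds, function(cc) {
    one(roster[roster$condition == cc, , drop = FALSE], cc)
  })
  out <- rbind(one(roster, "TOTAL"), do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("demographics_table", class(out))
  out
}

#' Render a summary table as markdown or CSV lines
#'
#' @param x a data frame (any of the summary tables).
#' @param format `"markdown"` or `"csv"`.
#' @return character vector of lines.
#' @export
render_table <- function(x, format = c("markdown", "csv")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  for (col in names(df)) {
    v <- df[[col]]
    df[[col]] <- ifelse(is.na(v), "—", as.character(v))
  }
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    return(out)
  }
  widths <- pmax(nchar(names(df)),
                 vapply(df, function(v) max(nchar(v), 0L), integer(1)))
  pad <- function(v, w) formatC(v, width = w, flag = "-")
  header <- paste0("| ", paste(mapply(pad, names(df), widths),
                               collapse = " | "), " |")
  sep <- paste0("|", paste(vapply(widths + 2L, function(w) {
    strrep("-", w)
  }, ""), collapse = "|"), "|")
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(mapply(pad, unlist(df[i, ]), widths),
                       collapse = " | "), " |")
  }, "")
  c(header, sep, body)
}
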