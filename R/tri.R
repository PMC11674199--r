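#' Tri-state criterion values
#'
#' Every case-definition criterion carries one of three states:
#' `"present"`, `"absent"` or `"unknown"`. `"unknown"` is the universal
#' default for any criterion that a record does not mention -- level-4
#' (insufficient information) classifications arise only from unknowns,
#' never from silently assumed negatives.
#'
#' @return `tri_levels()` returns the three state tokens in canonical order.
#' @export
tri_levels <- function() c("present", "absent", "unknown")

#' Parse a line-list cell into a tri-state value
#'
#' Line-list CSV cells use a small closed vocabulary (case-insensitive):
#' `"yes"`/`"y"`/`"1"` map to present, `"no"`/`"n"`/`"0"` to absent, and
#' `""`/`"unknown"`/`"na"` to unknown. The canonical tokens
#' `"present"`/`"absent"` are also accepted so that round-tripped data
#' re-parse.
#'
#' @param token character vector of raw cells.
#' @param context optional string naming the row/column, used in the error
#'   message for unrecognized tokens.
#' @return character vector of `"present"`, `"absent"`, `"unknown"`.
#' @examples
#' tri_from_token(c("yes", "", "NO"))
#' @export
tri_from_token <- function(token, context = NULL) {
  tok <- tolower(trimws(as.character(token)))
  tok[is.na(token)] <- ""
  out <- rep(NA_character_, length(tok))
  out[tok %in% c("yes", "y", "1", "present", "true")] <- "present"
  out[tok %in% c("no", "n", "0", "absent", "false")] <- "absent"
  out[tok %in% c("", "unknown", "na", "unk", "u", "?")] <- "unknown"
  bad <- which(is.na(out))
  if (length(bad)) {
    where <- if (is.null(context)) "" else paste0(" at ", context)
    stop(sprintf("unrecognized tri-state token '%s'%s", token[bad[1]], where),
         call. = FALSE)
  }
  out
}

#' Serialize tri-state values to line-list tokens
#'
#' Inverse of [tri_from_token()]: present -> `"yes"`, absent -> `"no"`,
#' unknown -> `""` (a blank cell means "not recorded").
#'
#' @param tri character vector of tri-state values.
#' @return character vector of line-list tokens.
#' @export
tri_to_token <- function(tri) {
  stopifnot(all(tri %in% tri_levels()))
  c(present = "yes", absent = "no", unknown = "")[tri]
}

# present -> TRUE, absent -> FALSE, unknown -> NA (strong-Kleene carrier)
tri_to_logical <- function(tri) {
  c(present = TRUE, absent = FALSE, unknown = NA)[tri]
}

assert_tri <- function(x, what = "value") {
  bad <- setdiff(unique(x), tri_levels())
  if (length(bad)) {
    stop(sprintf("invalid tri-state %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
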