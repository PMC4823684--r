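#' Tri-state clinical sign values
#'
#' Field-collected clinical signs are recorded as one of three states:
#' `"present"`, `"absent"` or `"unknown"`. `"unknown"` (not observed /
#' not recorded) is distinct from `"absent"` (observed to be absent):
#' the classifiers treat unknown as absent when descending the cause
#' hierarchy, but every rule trace flags decisions that rested on
#' unknown inputs so the uncertainty stays auditable.
#'
#' @return Character vector of the three allowed states, in canonical
#'   order `present`, `absent`, `unknown`.
#' @export
#' @examples
#' tristate_levels()
tristate_levels <- function() c("present", "absent", "unknown")

#' Coerce raw values to tri-state sign values
#'
#' Accepts the encodings used in field CSVs: `yes`/`no`/blank,
#' `y`/`n`, `true`/`false`, `1`/`0`, logicals, and the canonical
#' `present`/`absent`/`unknown`. Blank strings and `NA` map to
#' `"unknown"` (the sign was not recorded). Case-insensitive.
#'
#' @param x vector of raw values (character, logical or numeric).
#' @return Character vector of tri-state values.
#' @export
#' @examples
#' as_tristate(c("yes", "no", "", NA, "Present", "0", "TRUE"))
as_tristate <- function(x) {
  if (is.logical(x)) {
    out <- ifelse(is.na(x), "unknown", ifelse(x, "present", "absent"))
    return(out)
  }
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[is.na(x) | x %in% c("", "na", "unknown", "unk", "missing", ".")] <- "unknown"
  out[x %in% c("present", "yes", "y", "true", "t", "1")] <- "present"
  out[x %in% c("absent", "no", "n", "false", "f", "0")] <- "absent"
  bad <- is.na(out)
  if (any(bad)) {
    stop("unrecognised tri-state value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Logical OR over tri-state sign values
#'
#' The disjunction used throughout the classifiers to pool component
#' signs (e.g. "any sign of life", "any trauma indicator"):
#' `present` if any input is present; otherwise `unknown` if any input
#' is unknown; otherwise `absent`. The operation is commutative,
#' associative and idempotent, and `present` is absorbing.
#'
#' @param signs character vector (or list) of tri-state values;
#'   must be non-empty.
#' @return A single tri-state value.
#' @export
#' @examples
#' tristate_any(c("absent", "present"))  # "present"
#' tristate_any(c("unknown", "absent"))  # "unknown"
tristate_any <- function(signs) {
  signs <- unlist(signs, use.names = FALSE)
  if (length(signs) == 0L) {
    stop("tristate_any() requires at least one sign", call. = FALSE)
  }
  bad <- !signs %in% tristate_levels()
  if (any(bad)) {
    stop("invalid tri-state value(s): ",
         paste(unique(signs[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(signs == "present")) return("present")
  if (any(signs == "unknown")) return("unknown")
  "absent"
}

# Internal helpers: the hierarchy descends on "unknown treated as absent",
# so rules fire only on "present"; ts_uncertain() marks trace flags.
ts_present <- function(x) !is.na(x) & x == "present"
ts_absent <- function(x) !is.na(x) & x == "absent"
ts_unknown <- function(x) is.na(x) | x == "unknown"
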