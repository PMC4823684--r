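detect_format <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
}

#' Read case records from CSV or JSON-lines
#'
#' Reads a case file against the published column dictionary
#' ([case_schema()]). The CSV dialect is UTF-8, comma-delimited, with
#' a mandatory header row; an empty cell means missing/unknown and
#' boolean signs are `yes`/`no`/blank. JSON-lines mirrors the schema
#' with `null` for unknown. Unknown columns are warned about and
#' carried through; missing mandatory columns (`case_id`,
#' `subject_kind`) are fatal. A malformed JSON line is skipped and
#' reported, never fatal: the remaining rows are still returned.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return data.frame of raw case columns (character/numeric), with
#'   attribute `"read_issues"`: a data.frame (`row`, `message`) of
#'   skipped/malformed rows. Row order preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("case_id,subject_kind,pregnancy_weeks_at_death",
#'              "m1,mother,17"), f)
#' read_cases(f)
read_cases <- function(path, format = c("auto", "csv", "jsonl")) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  format <- detect_format(path, format)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, na.strings = character(),
                          fileEncoding = "UTF-8")
    issues <- data.frame(row = integer(), message = character(),
                         stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines_keep <- which(nzchar(trimws(lines)))
    parsed <- vector("list", length(lines_keep))
    bad <- logical(length(lines_keep))
    msgs <- character(length(lines_keep))
    for (k in seq_along(lines_keep)) {
      p <- tryCatch(jsonlite::fromJSON(lines[lines_keep[k]],
                                       simplifyVector = TRUE),
                    error = function(e) e)
      if (inherits(p, "error") || !is.list(p)) {
        bad[k] <- TRUE
        msgs[k] <- if (inherits(p, "error")) conditionMessage(p) else
          "line is not a JSON object"
      } else {
        parsed[[k]] <- p
      }
    }
    issues <- data.frame(row = lines_keep[bad],
                         message = paste0("malformed JSON line: ",
                                          msgs[bad]),
                         stringsAsFactors = FALSE)
    parsed <- parsed[!bad]
    fields <- unique(unlist(lapply(parsed, names)))
    if (length(parsed) == 0L) {
      df <- data.frame(case_id = character(), subject_kind = character(),
                       stringsAsFactors = FALSE)
    } else {
      df <- stats::setNames(as.data.frame(
        lapply(fields, function(f) {
          vapply(parsed, function(p) {
            v <- p[[f]]
            if (is.null(v) || length(v) != 1L ||
                (is.atomic(v) && is.na(v))) ""
            else as.character(v)
          }, "")
        }), stringsAsFactors = FALSE), fields)
    }
  }
  need <- c("case_id", "subject_kind")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("mandatory column(s) missing from ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  known <- c(case_schema()$field, "true_death_type", "true_cause")
  extra <- setdiff(names(df), known)
  if (length(extra) > 0L) {
    warning("unknown column(s) ignored by the classifier: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  attr(df, "read_issues") <- issues
  df
}

#' Write a table of assignments (or cases) to CSV or JSON-lines
#'
#' CSV writes empty cells for `NA` (the dialect's missing value);
#' JSON-lines writes one object per row with `null` for missing. A
#' write/read/write round trip is byte-identical, which is what makes
#' batch outputs diffable across ruleset versions.
#'
#' @param df data.frame (e.g. from [classify_batch()]).
#' @param path output file.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, format = c("auto", "csv", "jsonl")) {
  format <- detect_format(path, format)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      row <- as.list(df[i, , drop = FALSE])
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  }
  invisible(path)
}
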