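#' Cause labels per death type
#'
#' The closed cause vocabularies, in hierarchy (precedence) order, for
#' each death type. These orders are the orders in which the rules are
#' evaluated and in which summaries report categories.
#'
#' @param death_type one of `"stillbirth"`, `"neonatal"`, `"maternal"`.
#' @return Character vector of cause labels, highest precedence first,
#'   ending in `"unknown"`.
#' @export
#' @examples
#' cause_labels("maternal")
cause_labels <- function(death_type) {
  switch(match.arg(death_type, c("stillbirth", "neonatal", "maternal")),
    stillbirth = c("trauma", "congenital_anomaly", "infection", "asphyxia",
                   "complications_of_preterm_labor", "unknown"),
    neonatal = c("congenital_anomaly", "infection", "asphyxia",
                 "complications_of_prematurity", "unknown"),
    maternal = c("trauma", "abortion_related", "eclampsia", "hemorrhage",
                 "infection", "preeclampsia_hypertensive", "thromboembolism",
                 "medical_condition", "unknown")
  )
}

#' Classify a single case record
#'
#' Runs validation, triage, and the matching cause hierarchy. Records
#' with validation errors, and records triaged outside the system
#' (miscarriage/abortion; live-born deaths at 28 days or more;
#' records with no usable triage fields), still yield an assignment
#' -- with `cod_primary` `NA` and the reason recorded -- so that a
#' batch is never aborted by one bad row.
#'
#' @param record a `case_record`.
#' @param rs a `cod_ruleset`.
#' @param validate run [validate_record()] first (default `TRUE`);
#'   errors make the case not classifiable.
#' @return A `cause_assignment`.
#' @export
#' @examples
#' rs <- default_ruleset()
#' r <- case_record("m1", "mother", pregnancy_weeks_at_death = 36,
#'                  seizure_or_unresponsive = "yes",
#'                  hemorrhage_gt_1000cc = "yes")
#' classify_case(r, rs)$cod_primary  # eclampsia: seizures take precedence
classify_case <- function(record, rs = default_ruleset(), validate = TRUE) {
  if (validate) {
    iss <- validate_record(record)
    if (!record_is_classifiable(iss)) {
      msg <- paste(iss$message[iss$severity == "error"], collapse = "; ")
      dtype <- death_type("not_classifiable",
                          reason = paste0("validation error: ", msg))
      tr <- trace_add(new_trace(), "validation", FALSE, record, character())
      return(cause_assignment(record, dtype, NA_character_, tr, rs))
    }
  }
  dtype <- triage(record, rs)
  switch(dtype$kind,
    stillbirth = classify_stillbirth(record, rs),
    neonatal_death = classify_neonatal(record, rs),
    maternal_death = classify_maternal(record, rs),
    miscarriage_abortion = {
      tr <- trace_add(new_trace(), "triage_miscarriage_abortion", TRUE,
                      record, c("gestational_age_weeks",
                                "birth_weight_grams"))
      cause_assignment(record, dtype, NA_character_, tr, rs)
    },
    {
      tr <- trace_add(new_trace(), "triage_not_classifiable", TRUE, record,
                      character())
      cause_assignment(record, dtype, NA_character_, tr, rs)
    }
  )
}

trace_string <- function(trace) {
  paste(paste0(trace$rule_id, ":", trace$outcome,
               ifelse(trace$unknown_inputs, "?", "")),
        collapse = "|")
}

# Coerce a raw data.frame (as read from CSV/JSONL) into case records.
# Returns list(records = <list>, issues = <data.frame row/field/message>)
# so parse failures are reported per row instead of aborting the batch.
df_to_records <- function(df) {
  sc <- case_schema()
  need <- c("case_id", "subject_kind")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("mandatory column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  issues <- data.frame(row = integer(), field = character(),
                       message = character(), stringsAsFactors = FALSE)
  cols <- list()
  for (i in seq_len(nrow(sc))) {
    f <- sc$field[i]
    ty <- sc$type[i]
    if (f %in% names(df)) {
      v <- df[[f]]
      if (ty == "tristate") {
        cols[[f]] <- as_tristate(v)
      } else if (ty %in% c("id", "enum")) {
        cols[[f]] <- as.character(v)
      } else {
        ch <- trimws(as.character(v))
        num <- suppressWarnings(as.numeric(ch))
        bad <- which(!is.na(ch) & nzchar(ch) & is.na(num))
        if (length(bad) > 0L) {
          issues <- rbind(issues, data.frame(
            row = bad, field = f,
            message = paste0("cannot parse '", ch[bad], "' as a number"),
            stringsAsFactors = FALSE))
        }
        cols[[f]] <- num
      }
    } else {
      cols[[f]] <- switch(ty,
        tristate = rep("unknown", n),
        id = rep(NA_character_, n),
        enum = rep(NA_character_, n),
        rep(NA_real_, n)
      )
    }
  }
  records <- lapply(seq_len(n), function(j) {
    rec <- lapply(cols, `[[`, j)
    class(rec) <- "case_record"
    rec
  })
  list(records = records, issues = issues)
}

#' Classify a batch of case records
#'
#' Dispatches every record through triage and the matching cause
#' hierarchy. Input order is preserved; per-record validation or
#' parse errors produce a `not_classifiable` row with the reasons,
#' never an aborted batch. Rerunning the same batch under a modified
#' ruleset (reclassification) is supported and changes assignments
#' only where an altered threshold is pivotal.
#'
#' @param x a data.frame of raw case columns (e.g. from
#'   [read_cases()]) or a list of `case_record` objects.
#' @param rs a `cod_ruleset`.
#' @param trace include the `rule_trace` column (default `TRUE`).
#' @return data.frame with one row per input record: `case_id`,
#'   `death_type`, `stillbirth_timing`, `cod_primary`, `cod_subtype`,
#'   `cod_subtypes_all`, `n_rules_on_unknown`, `rule_trace`,
#'   `reason`, `ruleset_version`.
#' @export
#' @examples
#' df <- data.frame(case_id = c("a", "b"),
#'                  subject_kind = c("fetus_or_neonate", "mother"),
#'                  gestational_age_weeks = c(38, NA),
#'                  signs_of_life = c("no", ""),
#'                  macerated = c("yes", ""),
#'                  pregnancy_weeks_at_death = c(NA, 17))
#' classify_batch(df)[, c("case_id", "death_type", "cod_primary")]
classify_batch <- function(x, rs = default_ruleset(), trace = TRUE) {
  if (is.data.frame(x)) {
    conv <- df_to_records(x)
    records <- conv$records
    parse_issues <- conv$issues
  } else {
    records <- x
    parse_issues <- data.frame(row = integer(), field = character(),
                               message = character(),
                               stringsAsFactors = FALSE)
  }
  n <- length(records)
  out <- data.frame(
    case_id = character(n), death_type = character(n),
    stillbirth_timing = character(n),
    cod_primary = rep(NA_character_, n),
    cod_subtype = rep(NA_character_, n), cod_subtypes_all = character(n),
    n_rules_on_unknown = integer(n),
    rule_trace = rep(NA_character_, n),
    reason = rep(NA_character_, n), ruleset_version = character(n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  for (j in seq_len(n)) {
    rec <- records[[j]]
    pi <- parse_issues[parse_issues$row == j, , drop = FALSE]
    if (nrow(pi) > 0L) {
      dtype <- death_type("not_classifiable",
        reason = paste0("parse error: ",
                        paste(pi$message, collapse = "; ")))
      a <- cause_assignment(rec, dtype, NA_character_,
                            trace_add(new_trace(), "parse", FALSE, rec,
                                      character()), rs)
    } else {
      a <- classify_case(rec, rs)
    }
    out$case_id[j] <- a$case_id
    out$death_type[j] <- a$death_type$kind
    out$stillbirth_timing[j] <- a$death_type$stillbirth_timing
    out$cod_primary[j] <- a$cod_primary
    out$cod_subtype[j] <- a$cod_subtype
    out$cod_subtypes_all[j] <- paste(a$cod_subtypes_all, collapse = ";")
    out$n_rules_on_unknown[j] <- sum(a$rule_trace$unknown_inputs)
    if (trace) out$rule_trace[j] <- trace_string(a$rule_trace)
    out$reason[j] <- a$death_type$reason
    out$ruleset_version[j] <- a$ruleset_version
  }
  out
}

#' Summarize a batch of cause assignments
#'
#' Per-death-type cause counts and fractions (stable hierarchy-order
#' categories), counts of unknown-cause assignments, of records
#' outside the system (miscarriage/abortion, not classifiable), and a
#' missingness diagnostic (how many assignments involved at least one
#' rule decided on unknown inputs).
#'
#' @param assignments data.frame from [classify_batch()].
#' @return An object of class `cohort_summary`: list with `n_total`,
#'   `by_cause` (data.frame `death_type`, `cause`, `n`, `fraction`;
#'   fractions sum to 1 within each death type), `n_unknown`,
#'   `n_miscarriage_abortion`, `n_not_classifiable`,
#'   `n_with_unknown_rule_inputs`.
#' @export
#' @examples
#' df <- data.frame(case_id = as.character(1:3),
#'                  subject_kind = "mother",
#'                  pregnancy_weeks_at_death = c(17, 38, 39),
#'                  hemorrhage_gt_1000cc = c("", "yes", ""))
#' summarize_cohort(classify_batch(df))
summarize_cohort <- function(assignments) {
  kinds <- c(stillbirth = "stillbirth", neonatal = "neonatal_death",
             maternal = "maternal_death")
  by_cause <- do.call(rbind, lapply(names(kinds), function(k) {
    sub <- assignments[assignments$death_type == kinds[[k]], , drop = FALSE]
    labs <- cause_labels(k)
    n <- vapply(labs, function(cz) sum(sub$cod_primary == cz, na.rm = TRUE),
                0L)
    data.frame(death_type = kinds[[k]], cause = labs, n = as.integer(n),
               fraction = if (nrow(sub) > 0L) n / nrow(sub) else 0,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(
    n_total = nrow(assignments),
    by_cause = by_cause,
    n_unknown = sum(assignments$cod_primary == "unknown", na.rm = TRUE),
    n_miscarriage_abortion =
      sum(assignments$death_type == "miscarriage_abortion"),
    n_not_classifiable = sum(assignments$death_type == "not_classifiable"),
    n_with_unknown_rule_inputs = sum(assignments$n_rules_on_unknown > 0)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", x$n_total, "assignment(s)\n")
  for (dt in unique(x$by_cause$death_type)) {
    sub <- x$by_cause[x$by_cause$death_type == dt, , drop = FALSE]
    tot <- sum(sub$n)
    if (tot == 0L) next
    cat(" ", dt, "(n =", tot, ")\n")
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-32s %6d  %6.1f%%\n", sub$cause[i], sub$n[i],
                  100 * sub$fraction[i]))
    }
  }
  cat("  miscarriage/abortion:", x$n_miscarriage_abortion,
      " not classifiable:", x$n_not_classifiable, "\n")
  cat("  assignments with rules decided on unknown inputs:",
      x$n_with_unknown_rule_inputs, "\n")
  invisible(x)
}
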