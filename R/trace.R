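# Rule-trace plumbing shared by the three classifiers. A trace entry
# is appended for every rule evaluated, in hierarchy order; evaluation
# stops at the first rule that fires, and that rule's cause is the
# primary cause. unknown_inputs marks rules whose decision rested on
# at least one unknown/missing input (unknown is treated as absent
# when the hierarchy descends, so the flag is the audit trail for
# that convention). Traces accumulate as plain lists and are
# materialized into a data.frame once per assignment.

new_trace <- function() list()

fmt_input <- function(record, f) {
  v <- record[[f]]
  if (is.numeric(v)) {
    paste0(f, "=", if (is.na(v)) "missing" else format(v))
  } else {
    paste0(f, "=", v)
  }
}

input_unknown <- function(record, f) {
  v <- record[[f]]
  if (is.numeric(v)) is.na(v) else ts_unknown(v)
}

trace_add <- function(trace, rule_id, fired, record, fields) {
  inputs <- if (length(fields) == 0L) "" else
    paste(vapply(fields, fmt_input, "", record = record), collapse = "; ")
  unknown <- length(fields) > 0L &&
    any(vapply(fields, input_unknown, TRUE, record = record))
  trace[[length(trace) + 1L]] <- list(rule_id = rule_id,
                                      outcome = if (fired) "fired" else
                                        "not_fired",
                                      inputs_used = inputs,
                                      unknown_inputs = unknown)
  trace
}

trace_df <- function(trace) {
  structure(list(
    rule_id = vapply(trace, `[[`, "", "rule_id"),
    outcome = vapply(trace, `[[`, "", "outcome"),
    inputs_used = vapply(trace, `[[`, "", "inputs_used"),
    unknown_inputs = vapply(trace, `[[`, TRUE, "unknown_inputs")
  ), class = "data.frame", row.names = seq_along(trace))
}

cause_assignment <- function(record, dtype, cod_primary, rule_trace, rs,
                             cod_subtype = NA_character_,
                             cod_subtypes_all = character()) {
  structure(list(
    case_id = record$case_id,
    death_type = dtype,
    cod_primary = cod_primary,
    cod_subtype = cod_subtype,
    cod_subtypes_all = cod_subtypes_all,
    rule_trace = trace_df(rule_trace),
    ruleset_version = rs$version
  ), class = "cause_assignment")
}

#' @export
print.cause_assignment <- function(x, ...) {
  cat("<cause_assignment>", x$case_id, "\n")
  cat("  death_type:     ", x$death_type$kind,
      if (x$death_type$kind == "stillbirth")
        paste0("(", x$death_type$stillbirth_timing, ")") else "", "\n")
  cat("  cod_primary:    ", x$cod_primary, "\n")
  if (!is.na(x$cod_subtype)) cat("  cod_subtype:    ", x$cod_subtype, "\n")
  if (length(x$cod_subtypes_all) > 0L)
    cat("  subtypes (all): ", paste(x$cod_subtypes_all, collapse = ", "), "\n")
  cat("  ruleset:        ", x$ruleset_version, "\n")
  cat("  rule trace:\n")
  for (i in seq_len(nrow(x$rule_trace))) {
    cat(sprintf("    %-28s %-9s %s%s\n", x$rule_trace$rule_id[i],
                x$rule_trace$outcome[i],
                x$rule_trace$inputs_used[i],
                if (x$rule_trace$unknown_inputs[i]) "  [unknown inputs]" else ""))
  }
  invisible(x)
}
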