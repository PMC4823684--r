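#' Case-record column dictionary
#'
#' The machine-readable schema for case records: one row per field
#' with its type, units and allowed values. CSV and JSON-lines
#' readers validate input against this dictionary, and
#' [write_case_schema()] exports it so that data-collection tools can
#' consume it. A copy ships with the package at
#' `system.file("extdata", "case_schema.csv", package = "codassign")`.
#'
#' Numeric sanity bounds (gestational age 4--50 weeks, birth weight
#' 100--8000 g, temperature 25--45 C) are validation limits chosen to
#' catch data-entry errors; they are not clinical thresholds.
#'
#' @return A data.frame with columns `field`, `type` (`id`, `enum`,
#'   `numeric`, `integer`, `tristate`), `units`, `allowed`, `lo`, `hi`,
#'   `description`.
#' @export
#' @examples
#' head(case_schema())
case_schema <- function() {
  if (!is.null(.schema_cache$df)) return(.schema_cache$df)
  .schema_cache$df <- build_case_schema()
  .schema_cache$df
}

.schema_cache <- new.env(parent = emptyenv())

build_case_schema <- function() {
  tri <- function(field, desc) {
    data.frame(field = field, type = "tristate", units = "",
               allowed = "present|absent|unknown", lo = NA_real_,
               hi = NA_real_, description = desc,
               stringsAsFactors = FALSE)
  }
  num <- function(field, units, lo, hi, desc) {
    data.frame(field = field, type = "numeric", units = units,
               allowed = "", lo = lo, hi = hi, description = desc,
               stringsAsFactors = FALSE)
  }
  rbind(
    data.frame(field = "case_id", type = "id", units = "", allowed = "",
               lo = NA_real_, hi = NA_real_,
               description = "unique case identifier",
               stringsAsFactors = FALSE),
    data.frame(field = "subject_kind", type = "enum", units = "",
               allowed = "fetus_or_neonate|mother", lo = NA_real_,
               hi = NA_real_,
               description = "who died: the fetus/neonate or the mother",
               stringsAsFactors = FALSE),
    num("gestational_age_weeks", "completed weeks", 4, 50,
        "gestational age at delivery"),
    num("birth_weight_grams", "g", 100, 8000, "birth weight"),
    tri("signs_of_life",
        "any sign of life at delivery: heartbeat, cry, breathing or movement"),
    tri("macerated", "maceration of the fetus at delivery"),
    num("age_at_death_days", "days", 0, 365,
        "age at death for live-born infants (completed days)"),
    tri("maternal_trauma",
        "maternal trauma during pregnancy: accident, assault or suicide"),
    tri("fetal_trauma_signs",
        paste("fetal trauma at delivery: severe bruising, cephalohematoma,",
              "sub-conjunctival hemorrhage, large caput or long-bone fracture")),
    tri("major_congenital_anomaly",
        paste("major visible anomaly: neural tube defect/anencephaly,",
              "abdominal wall defect or other visible defect")),
    tri("maternal_infection_signs",
        paste("maternal infection in pregnancy or delivery: malaria or",
              "syphilis positive, fever, chills, or significant",
              "vaginal/fetal odor at delivery")),
    tri("cond_preeclampsia_eclampsia",
        "maternal preeclampsia/eclampsia (BP >=140/90 with proteinuria)"),
    tri("cond_obstructed_or_prolonged_labor",
        "obstructed labor or labor lasting more than one day"),
    tri("cond_antepartum_hemorrhage",
        "heavy bleeding (>1000 cc) before delivery (abruption/previa)"),
    tri("cond_fetal_distress",
        paste("fetal distress in labor: decreased movements, bradycardia",
              "(<120 bpm), tachycardia (>160 bpm) or meconium staining")),
    tri("cond_cord_complication",
        "cord prolapse, cord around the neck, compression or rupture"),
    tri("cond_breech_presentation", "breech presentation"),
    tri("cond_twins", "twin (multiple) gestation"),
    num("temperature_celsius", "deg C", 25, 45,
        "neonatal body temperature, if measured"),
    tri("hot_to_touch", "neonate very warm to the touch"),
    tri("cool_to_touch", "neonate cool to the touch"),
    tri("seizures_ge_2_days",
        "fits or seizures starting 2 or more days after birth"),
    tri("umbilical_discharge_pus_bleeding",
        "cloudy discharge, pus or bleeding at the umbilical stump"),
    tri("pneumonia_signs",
        paste("pneumonia: chest x-ray, or poor feeding, irritability,",
              "tachypnea, retractions, grunting or hypoxemia")),
    tri("breathing_difficulty_or_no_cry",
        "breathing difficulty or no cry at birth"),
    tri("seizures_lt_2_days",
        "fits or seizures within 2 days of birth"),
    tri("resuscitation_at_birth",
        "bag-and-mask or other resuscitation effort at birth"),
    num("pregnancy_weeks_at_death", "completed weeks", 4, 50,
        paste("gestation at the mother's death (or at the end of the",
              "pregnancy for postpartum deaths)")),
    num("weeks_postpartum_at_death", "weeks", 0, 52,
        "weeks postpartum at the mother's death; 0/missing if pregnant"),
    tri("induced_abortion", "abortion was induced"),
    tri("ectopic_pregnancy", "ectopic pregnancy"),
    tri("seizure_or_unresponsive",
        "one or more convulsions or a state of unresponsiveness"),
    tri("hemorrhage_gt_1000cc",
        "blood loss over 1000 cc (about 4 cups) before or after delivery"),
    tri("preeclampsia_signs",
        paste("BP >=140/90 with proteinuria, headache; may include",
              "stroke, loss of consciousness or paralysis")),
    tri("acute_dyspnea_and_chest_pain",
        "acute shortness of breath together with chest pain"),
    tri("medical_condition",
        paste("coincident medical condition: cancer, cardiac disease,",
              "severe anemia, diabetes or renal disease"))
  )
}

#' @rdname case_schema
#' @param path file to write the dictionary to (CSV).
#' @export
write_case_schema <- function(path) {
  utils::write.csv(case_schema(), path, row.names = FALSE)
  invisible(path)
}

schema_tristate_fields <- function() {
  if (is.null(.schema_cache$tri)) {
    sc <- case_schema()
    .schema_cache$tri <- sc$field[sc$type == "tristate"]
  }
  .schema_cache$tri
}

schema_numeric_fields <- function() {
  sc <- case_schema()
  sc$field[sc$type == "numeric"]
}

#' Construct a single case record
#'
#' Builds a validated-shape case record: unspecified tri-state signs
#' default to `"unknown"` and unspecified numeric fields to `NA`
#' (missing). Values are coerced with [as_tristate()], so field
#' encodings (`yes`/`no`/blank) are accepted. Construction enforces
#' types only; range and consistency checks live in
#' [validate_record()].
#'
#' @param case_id unique identifier string.
#' @param subject_kind `"fetus_or_neonate"` or `"mother"`.
#' @param ... field values by schema name (see [case_schema()]).
#' @return An object of class `case_record` (a named list over the full
#'   schema).
#' @export
#' @examples
#' case_record("sb-1", "fetus_or_neonate",
#'             gestational_age_weeks = 36, signs_of_life = "no",
#'             macerated = "yes")
case_record <- function(case_id, subject_kind, ...) {
  sc <- case_schema()
  rec <- stats::setNames(vector("list", nrow(sc)), sc$field)
  for (i in seq_len(nrow(sc))) {
    rec[[i]] <- switch(sc$type[i],
      tristate = "unknown",
      NA_real_
    )
  }
  rec$case_id <- as.character(case_id)
  rec$subject_kind <- as.character(subject_kind)
  extra <- list(...)
  bad <- setdiff(names(extra), sc$field)
  if (length(bad) > 0L) {
    stop("unknown case-record field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (f in names(extra)) {
    ty <- sc$type[sc$field == f]
    v <- extra[[f]]
    rec[[f]] <- switch(ty,
      tristate = as_tristate(v),
      id = as.character(v),
      enum = as.character(v),
      as.numeric(v)
    )
    if (length(rec[[f]]) != 1L) {
      stop("field '", f, "' must be length 1", call. = FALSE)
    }
  }
  class(rec) <- "case_record"
  rec
}

#' @export
print.case_record <- function(x, ...) {
  cat("<case_record>", x$case_id, "(", x$subject_kind, ")\n")
  sc <- case_schema()
  for (f in sc$field[sc$type == "numeric"]) {
    if (!is.na(x[[f]])) cat(sprintf("  %-34s %g\n", f, x[[f]]))
  }
  for (f in sc$field[sc$type == "tristate"]) {
    if (x[[f]] != "unknown") cat(sprintf("  %-34s %s\n", f, x[[f]]))
  }
  invisible(x)
}

issues_df <- function(field = character(), severity = character(),
                      message = character()) {
  structure(list(field = field, severity = severity, message = message),
            class = "data.frame", row.names = seq_along(field))
}

no_issues <- function() issues_df()

#' Validate a case record
#'
#' Pure function returning a data.frame of validation issues, one row
#' per problem, with `severity` `"error"` or `"warning"`. Errors are
#' out-of-range numerics and invalid enumerations; a record with no
#' error-severity issues is classifiable. Internal inconsistencies
#' that field data can legitimately contain (signs of life recorded
#' together with maceration; mostly-unknown sign fields) are warnings:
#' the record is still classified, and the rule trace carries the
#' uncertainty.
#'
#' @param record a `case_record` (see [case_record()]).
#' @return data.frame with columns `field`, `severity`, `message`
#'   (zero rows when the record is clean).
#' @export
#' @examples
#' r <- case_record("x", "fetus_or_neonate", gestational_age_weeks = 200)
#' validate_record(r)
validate_record <- function(record) {
  sc <- case_schema()
  fld <- character(); sev <- character(); msg <- character()
  add <- function(field, severity, message) {
    fld[[length(fld) + 1L]] <<- field
    sev[[length(sev) + 1L]] <<- severity
    msg[[length(msg) + 1L]] <<- message
  }
  if (!record$subject_kind %in% c("fetus_or_neonate", "mother")) {
    add("subject_kind", "error",
        paste0("subject_kind must be fetus_or_neonate or mother, got '",
               record$subject_kind, "'"))
  }
  if (is.na(record$case_id) || !nzchar(record$case_id)) {
    add("case_id", "error", "case_id is empty")
  }
  for (i in which(sc$type == "numeric")) {
    f <- sc$field[i]
    v <- record[[f]]
    if (length(v) != 1L) {
      add(f, "error", "field must be length 1")
      next
    }
    if (is.na(v)) next
    if (!is.numeric(v)) {
      add(f, "error", "field must be numeric")
    } else if (v < sc$lo[i] || v > sc$hi[i]) {
      add(f, "error",
          sprintf("%s = %g outside plausible range [%g, %g] %s",
                  f, v, sc$lo[i], sc$hi[i], sc$units[i]))
    }
  }
  tri_fields <- schema_tristate_fields()
  tri_vals <- unlist(record[tri_fields], use.names = FALSE)
  ok <- tri_vals %in% tristate_levels()
  if (length(tri_vals) != length(tri_fields) || !all(ok)) {
    for (f in tri_fields) {
      v <- record[[f]]
      if (length(v) != 1L || !v %in% tristate_levels()) {
        add(f, "error", "tri-state field must be present/absent/unknown")
      }
    }
  }
  # consistency warnings (classification still proceeds)
  if (ts_present(record$signs_of_life) && ts_present(record$macerated)) {
    add("macerated", "warning",
        "signs of life recorded together with maceration")
  }
  if (record$subject_kind == "fetus_or_neonate" &&
      !is.na(record$age_at_death_days) && record$age_at_death_days >= 28) {
    add("age_at_death_days", "warning",
        "death at >=28 days is outside the neonatal period")
  }
  if (mean(tri_vals == "unknown") > 0.5) {
    add("(record)", "warning",
        "more than half of sign fields are unknown")
  }
  issues_df(fld, sev, msg)
}

record_is_classifiable <- function(issues) {
  !any(issues$severity == "error")
}
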