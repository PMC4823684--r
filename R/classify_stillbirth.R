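# Condition set feeding the stillbirth asphyxia rule, in subtype
# precedence order (the first present condition becomes the primary
# subtype; all present conditions are reported).
stillbirth_asphyxia_conditions <- function() {
  c("preeclampsia_eclampsia", "obstructed_or_prolonged_labor",
    "antepartum_hemorrhage", "fetal_distress", "cord_complication")
}

#' Classify the cause of a stillbirth
#'
#' Applies the stillbirth cause hierarchy, in strict precedence
#' order, stopping at the first rule that fires:
#' \enumerate{
#'   \item \strong{trauma} -- maternal trauma (accident, assault,
#'     suicide) or fetal trauma signs; takes precedence over every
#'     other cause.
#'   \item \strong{congenital_anomaly} -- major visible anomaly.
#'   \item \strong{infection} -- maternal infection signs (malaria or
#'     syphilis positive, fever, significant vaginal/fetal odor).
#'   \item \strong{asphyxia} -- any maternal or fetal condition highly
#'     predictive of intrauterine asphyxia: preeclampsia/eclampsia,
#'     obstructed or prolonged labor, antepartum hemorrhage, fetal
#'     distress, or a cord complication. The first present condition
#'     (in that fixed order) is recorded as the subtype; all present
#'     conditions go into `cod_subtypes_all`.
#'   \item \strong{complications_of_preterm_labor} -- gestational age
#'     below 32 weeks or birth weight below 1500 g, with the fetus
#'     not macerated (i.e. evidence it died in labor). Maceration
#'     unknown does not satisfy this rule.
#'   \item \strong{unknown} -- no other cause identified.
#' }
#'
#' @param record a `case_record` that triages to stillbirth.
#' @param rs a `cod_ruleset`.
#' @return A `cause_assignment` with the primary cause, subtype(s),
#'   ordered rule trace and ruleset version.
#' @export
#' @examples
#' rs <- default_ruleset()
#' r <- case_record("sb", "fetus_or_neonate", gestational_age_weeks = 38,
#'                  signs_of_life = "absent", macerated = "absent",
#'                  cond_cord_complication = "present")
#' classify_stillbirth(r, rs)$cod_primary
classify_stillbirth <- function(record, rs = default_ruleset()) {
  dtype <- triage(record, rs)
  if (dtype$kind != "stillbirth") {
    stop("classify_stillbirth() called on a record that triages to ",
         dtype$kind, call. = FALSE)
  }
  tr <- trace_add(new_trace(), "triage_stillbirth", TRUE, record,
                  c("gestational_age_weeks", "birth_weight_grams",
                    "signs_of_life", "macerated"))

  trauma <- tristate_any(c(record$maternal_trauma, record$fetal_trauma_signs))
  fired <- trauma == "present"
  tr <- trace_add(tr, "trauma", fired, record,
                  c("maternal_trauma", "fetal_trauma_signs"))
  if (fired) return(cause_assignment(record, dtype, "trauma", tr, rs))

  fired <- ts_present(record$major_congenital_anomaly)
  tr <- trace_add(tr, "congenital_anomaly", fired, record,
                  "major_congenital_anomaly")
  if (fired) return(cause_assignment(record, dtype, "congenital_anomaly", tr, rs))

  fired <- ts_present(record$maternal_infection_signs)
  tr <- trace_add(tr, "infection", fired, record, "maternal_infection_signs")
  if (fired) return(cause_assignment(record, dtype, "infection", tr, rs))

  conds <- stillbirth_asphyxia_conditions()
  cond_fields <- paste0("cond_", conds)
  present <- conds[vapply(cond_fields, function(f) ts_present(record[[f]]),
                          TRUE)]
  fired <- length(present) > 0L
  tr <- trace_add(tr, "asphyxia", fired, record, cond_fields)
  if (fired) {
    return(cause_assignment(record, dtype, "asphyxia", tr, rs,
                            cod_subtype = present[1L],
                            cod_subtypes_all = present))
  }

  ga <- record$gestational_age_weeks
  bw <- record$birth_weight_grams
  small <- (!is.na(ga) && ga < rs$stillbirth_preterm_weeks) ||
           (!is.na(bw) && bw < rs$stillbirth_preterm_grams)
  fired <- small && ts_absent(record$macerated)
  tr <- trace_add(tr, "preterm_labor", fired, record,
                  c("gestational_age_weeks", "birth_weight_grams",
                    "macerated"))
  if (fired) {
    return(cause_assignment(record, dtype, "complications_of_preterm_labor",
                            tr, rs))
  }

  tr <- trace_add(tr, "unknown", TRUE, record, character())
  cause_assignment(record, dtype, "unknown", tr, rs)
}
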