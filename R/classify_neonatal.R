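# Maternal/fetal conditions that may be associated with birth
# asphyxia in a neonate, in the order used to pick the primary
# associated condition when several are present.
neonatal_asphyxia_conditions <- function() {
  c("preeclampsia_eclampsia", "obstructed_or_prolonged_labor",
    "antepartum_hemorrhage", "fetal_distress", "cord_complication",
    "breech_presentation", "twins")
}

# Infection subtype precedence: tetanus > omphalitis > pneumonia >
# sepsis. Late seizures (>=2 days after birth) are the field sign of
# neonatal tetanus; umbilical pus/discharge indicates omphalitis;
# fever or hypothermia without a more specific sign reads as sepsis.
neonatal_infection_subtypes <- function(record, rs) {
  fever <- (!is.na(record$temperature_celsius) &&
            record$temperature_celsius > rs$fever_celsius) ||
           ts_present(record$hot_to_touch)
  hypo <- (!is.na(record$temperature_celsius) &&
           record$temperature_celsius < rs$hypothermia_celsius) ||
          ts_present(record$cool_to_touch)
  subs <- c(
    tetanus = ts_present(record$seizures_ge_2_days),
    omphalitis = ts_present(record$umbilical_discharge_pus_bleeding),
    pneumonia = ts_present(record$pneumonia_signs),
    sepsis = fever || hypo
  )
  names(subs)[subs]
}

#' Classify the cause of a neonatal death
#'
#' Applies the neonatal-death cause hierarchy, in strict precedence
#' order, stopping at the first rule that fires:
#' \enumerate{
#'   \item \strong{congenital_anomaly} -- major visible anomaly takes
#'     precedence over every other cause (an anencephalic infant who
#'     also has infection signs died of the anomaly).
#'   \item \strong{infection} -- fever (measured >37.5 C or very warm
#'     to touch), hypothermia (<35.5 C or cool to touch), seizures
#'     starting at 2 or more days of age, umbilical pus/discharge, or
#'     pneumonia signs. Subtype precedence: tetanus > omphalitis >
#'     pneumonia > sepsis; all present subtypes are reported.
#'   \item \strong{complications_of_prematurity} (small or early) --
#'     birth weight below 2000 g or gestational age below 34 weeks:
#'     prematurity is assigned unconditionally, regardless of
#'     respiratory distress, because RDS is common in these infants
#'     and pneumonia has already been considered and rejected.
#'   \item \strong{asphyxia} -- in larger infants (at least 2000 g and
#'     34 weeks on the available fields): breathing difficulty or no
#'     cry at birth, seizures within 2 days of birth, or resuscitation
#'     at birth. Any present maternal/fetal condition associated with
#'     asphyxia (preeclampsia/eclampsia, obstructed labor, antepartum
#'     hemorrhage, fetal distress, cord complication, breech, twins)
#'     is recorded, the first as `cod_subtype`.
#'   \item \strong{complications_of_prematurity} (late preterm) -- a
#'     34--36-week infant with none of the above: below 37 weeks a
#'     death without anomaly or infection is never unknown, because
#'     prematurity is always considered the primary contributor.
#'   \item \strong{unknown} -- term infant (37 weeks or more), no
#'     cause identified.
#' }
#'
#' When gestational age is missing the weight criterion is used
#' alone, and vice versa; with both missing the infant is treated as
#' term for the size split and the rule trace flags the assumption.
#'
#' @param record a `case_record` that triages to neonatal death.
#' @param rs a `cod_ruleset`.
#' @return A `cause_assignment`.
#' @export
#' @examples
#' rs <- default_ruleset()
#' r <- case_record("nn", "fetus_or_neonate", gestational_age_weeks = 40,
#'                  birth_weight_grams = 3200, signs_of_life = "present",
#'                  age_at_death_days = 1,
#'                  breathing_difficulty_or_no_cry = "present",
#'                  cond_obstructed_or_prolonged_labor = "present")
#' classify_neonatal(r, rs)$cod_primary
classify_neonatal <- function(record, rs = default_ruleset()) {
  dtype <- triage(record, rs)
  if (dtype$kind != "neonatal_death") {
    stop("classify_neonatal() called on a record that triages to ",
         dtype$kind, call. = FALSE)
  }
  tr <- trace_add(new_trace(), "triage_neonatal", TRUE, record,
                  c("signs_of_life", "age_at_death_days"))

  fired <- ts_present(record$major_congenital_anomaly)
  tr <- trace_add(tr, "congenital_anomaly", fired, record,
                  "major_congenital_anomaly")
  if (fired) return(cause_assignment(record, dtype, "congenital_anomaly", tr, rs))

  subs <- neonatal_infection_subtypes(record, rs)
  fired <- length(subs) > 0L
  tr <- trace_add(tr, "infection", fired, record,
                  c("temperature_celsius", "hot_to_touch", "cool_to_touch",
                    "seizures_ge_2_days", "umbilical_discharge_pus_bleeding",
                    "pneumonia_signs"))
  if (fired) {
    return(cause_assignment(record, dtype, "infection", tr, rs,
                            cod_subtype = subs[1L],
                            cod_subtypes_all = subs))
  }

  ga <- record$gestational_age_weeks
  bw <- record$birth_weight_grams
  # small/early branch wins over the asphyxia branch when GA and BW
  # disagree (e.g. 35 wk, 1800 g): prematurity is unconditional for
  # small infants. Both missing -> treated as term, flagged in trace.
  small <- (!is.na(bw) && bw < rs$neonatal_prematurity_grams) ||
           (!is.na(ga) && ga < rs$neonatal_prematurity_weeks)
  tr <- trace_add(tr, "prematurity_small_or_early", small, record,
                  c("gestational_age_weeks", "birth_weight_grams"))
  if (small) {
    return(cause_assignment(record, dtype, "complications_of_prematurity",
                            tr, rs))
  }

  asphyx <- ts_present(record$breathing_difficulty_or_no_cry) ||
            ts_present(record$seizures_lt_2_days) ||
            ts_present(record$resuscitation_at_birth)
  tr <- trace_add(tr, "asphyxia", asphyx, record,
                  c("breathing_difficulty_or_no_cry", "seizures_lt_2_days",
                    "resuscitation_at_birth"))
  if (asphyx) {
    conds <- neonatal_asphyxia_conditions()
    present <- conds[vapply(paste0("cond_", conds),
                            function(f) ts_present(record[[f]]), TRUE)]
    return(cause_assignment(record, dtype, "asphyxia", tr, rs,
                            cod_subtype = if (length(present) > 0L)
                              present[1L] else NA_character_,
                            cod_subtypes_all = present))
  }

  late_preterm <- !is.na(ga) && ga < rs$term_weeks
  tr <- trace_add(tr, "prematurity_late_preterm", late_preterm, record,
                  "gestational_age_weeks")
  if (late_preterm) {
    return(cause_assignment(record, dtype, "complications_of_prematurity",
                            tr, rs))
  }

  tr <- trace_add(tr, "unknown", TRUE, record, character())
  cause_assignment(record, dtype, "unknown", tr, rs)
}
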