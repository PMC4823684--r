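death_type <- function(kind, stillbirth_timing = "not_applicable",
                       reason = NA_character_) {
  stopifnot(kind %in% c("miscarriage_abortion", "stillbirth",
                        "neonatal_death", "maternal_death",
                        "not_classifiable"))
  stopifnot(stillbirth_timing %in% c("antepartum", "intrapartum_or_recent",
                                     "indeterminate", "not_applicable"))
  if ((kind == "stillbirth") != (stillbirth_timing != "not_applicable")) {
    stop("stillbirth_timing applies to stillbirths only", call. = FALSE)
  }
  structure(list(kind = kind, stillbirth_timing = stillbirth_timing,
                 reason = reason),
            class = "death_type")
}

#' @export
print.death_type <- function(x, ...) {
  cat("<death_type>", x$kind)
  if (x$kind == "stillbirth") cat(" (", x$stillbirth_timing, ")", sep = "")
  if (!is.na(x$reason)) cat(" -", x$reason)
  cat("\n")
  invisible(x)
}

#' Triage a case record to a death type
#'
#' Decides which cause hierarchy applies to a record. Mothers are
#' maternal deaths (provided death occurred during pregnancy or
#' within the postpartum window, 6 weeks by default). For a fetus or
#' neonate the boundary between miscarriage/abortion and the
#' classifiable outcomes is 20 completed weeks gestation, falling
#' back to 500 g birth weight only when gestational age is
#' unavailable (gestational age, when present, always dominates).
#' At or above that boundary, signs of life at delivery (heartbeat,
#' cry, breathing or movement) separate a neonatal death (live birth,
#' death before 28 days) from a stillbirth; absent or unobserved
#' signs of life triage conservatively to stillbirth. Live-born
#' infants dying at 28 days or later are outside the system and
#' return `not_classifiable`, as do records lacking gestational age,
#' birth weight and signs-of-life information entirely.
#'
#' @param record a `case_record` that passed [validate_record()]
#'   without errors.
#' @param rs a `cod_ruleset`.
#' @return A `death_type`: list with `kind` (one of
#'   `miscarriage_abortion`, `stillbirth`, `neonatal_death`,
#'   `maternal_death`, `not_classifiable`), `stillbirth_timing`
#'   (see [stillbirth_timing()]; `not_applicable` unless a
#'   stillbirth) and `reason` (populated for `not_classifiable`).
#' @export
#' @examples
#' rs <- default_ruleset()
#' triage(case_record("a", "fetus_or_neonate",
#'                    gestational_age_weeks = 18,
#'                    signs_of_life = "absent"), rs)$kind
#' triage(case_record("b", "fetus_or_neonate", signs_of_life = "present",
#'                    gestational_age_weeks = 39,
#'                    age_at_death_days = 3), rs)$kind
triage <- function(record, rs = default_ruleset()) {
  if (record$subject_kind == "mother") {
    wp <- record$weeks_postpartum_at_death
    if (!is.na(wp) && wp > rs$maternal_postpartum_weeks) {
      return(death_type("not_classifiable",
        reason = sprintf("death at %g weeks postpartum is beyond the %g-week window",
                         wp, rs$maternal_postpartum_weeks)))
    }
    return(death_type("maternal_death"))
  }
  ga <- record$gestational_age_weeks
  bw <- record$birth_weight_grams
  sol <- record$signs_of_life
  below <- if (!is.na(ga)) {
    ga < rs$stillbirth_min_weeks          # GA dominates when present
  } else if (!is.na(bw)) {
    bw < rs$stillbirth_min_grams
  } else {
    NA
  }
  if (isTRUE(below)) {
    return(death_type("miscarriage_abortion"))
  }
  if (ts_present(sol)) {
    age <- record$age_at_death_days
    if (is.na(age)) {
      return(death_type("not_classifiable",
        reason = "live-born infant with age at death missing"))
    }
    if (age < rs$neonatal_period_days) {
      return(death_type("neonatal_death"))
    }
    return(death_type("not_classifiable",
      reason = sprintf("live-born death at %g days is outside the %g-day neonatal period",
                       age, rs$neonatal_period_days)))
  }
  if (is.na(below)) {
    return(death_type("not_classifiable",
      reason = "no gestational age, no birth weight and no signs-of-life information"))
  }
  death_type("stillbirth", stillbirth_timing = stillbirth_timing(record, rs))
}

#' Antepartum vs intrapartum timing of a stillbirth
#'
#' Maceration of the fetus indicates in-utero retention, read as
#' death more than 12 hours before delivery and therefore likely
#' antepartum; a non-macerated stillbirth likely died in labor or
#' shortly before (`intrapartum_or_recent`); when maceration was not
#' assessed the timing is `indeterminate`.
#'
#' @inheritParams triage
#' @return One of `"antepartum"`, `"intrapartum_or_recent"`,
#'   `"indeterminate"`.
#' @export
#' @examples
#' rs <- default_ruleset()
#' r <- case_record("s", "fetus_or_neonate", gestational_age_weeks = 34,
#'                  signs_of_life = "absent", macerated = "present")
#' stillbirth_timing(r, rs)
stillbirth_timing <- function(record, rs = default_ruleset()) {
  m <- record$macerated
  if (ts_present(m)) return("antepartum")
  if (ts_absent(m)) return("intrapartum_or_recent")
  "indeterminate"
}
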