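#' Classify the cause of a maternal death
#'
#' Applies the maternal-death cause hierarchy in strict precedence
#' order, stopping at the first rule that fires:
#' \enumerate{
#'   \item \strong{trauma} -- accident, assault or suicide takes
#'     precedence over every other cause.
#'   \item \strong{abortion_related} -- the pregnancy was under 20
#'     weeks at death (or at its end, for postpartum deaths), the
#'     pregnancy was ectopic, or an abortion was induced at any
#'     gestation. This overrides everything below: a woman who dies
#'     at 18 weeks of hemorrhage and sepsis is an abortion-related
#'     death.
#'   \item \strong{eclampsia} -- one or more convulsions or a state
#'     of unresponsiveness.
#'   \item \strong{hemorrhage} -- blood loss over 1000 cc (about 4
#'     cups) before or after delivery.
#'   \item \strong{infection} -- malaria or syphilis evidence, fever,
#'     chills, or significant vaginal/fetal odor at delivery.
#'   \item \strong{preeclampsia_hypertensive} -- hypertension
#'     (>=140/90) with proteinuria, headache, stroke or loss of
#'     consciousness, without a seizure. Preeclampsia alone ranks
#'     below hemorrhage and infection; a seizure promotes the death
#'     to eclampsia at rank 3.
#'   \item \strong{thromboembolism} -- acute shortness of breath
#'     together with chest pain, with no other cause identified.
#'   \item \strong{medical_condition} -- a coincident condition such
#'     as cancer, cardiac disease, severe anemia, diabetes or renal
#'     disease.
#'   \item \strong{unknown} -- no cause identified.
#' }
#'
#' Obstructed labor and ruptured uterus are deliberately not maternal
#' causes here: such deaths surface through the infection or
#' hemorrhage they produce.
#'
#' @param record a `case_record` for a mother that triages to
#'   maternal death (death during pregnancy or within 6 weeks
#'   postpartum).
#' @param rs a `cod_ruleset`.
#' @return A `cause_assignment`.
#' @export
#' @examples
#' rs <- default_ruleset()
#' r <- case_record("m", "mother", pregnancy_weeks_at_death = 18,
#'                  hemorrhage_gt_1000cc = "present",
#'                  maternal_infection_signs = "present")
#' classify_maternal(r, rs)$cod_primary  # abortion_related
classify_maternal <- function(record, rs = default_ruleset()) {
  dtype <- triage(record, rs)
  if (dtype$kind != "maternal_death") {
    stop("classify_maternal() called on a record that triages to ",
         dtype$kind, call. = FALSE)
  }
  tr <- trace_add(new_trace(), "triage_maternal", TRUE, record,
                  c("pregnancy_weeks_at_death", "weeks_postpartum_at_death"))

  fired <- ts_present(record$maternal_trauma)
  tr <- trace_add(tr, "trauma", fired, record, "maternal_trauma")
  if (fired) return(cause_assignment(record, dtype, "trauma", tr, rs))

  wk <- record$pregnancy_weeks_at_death
  fired <- (!is.na(wk) && wk < rs$maternal_abortion_weeks) ||
           ts_present(record$ectopic_pregnancy) ||
           ts_present(record$induced_abortion)
  tr <- trace_add(tr, "abortion_related", fired, record,
                  c("pregnancy_weeks_at_death", "ectopic_pregnancy",
                    "induced_abortion"))
  if (fired) return(cause_assignment(record, dtype, "abortion_related", tr, rs))

  fired <- ts_present(record$seizure_or_unresponsive)
  tr <- trace_add(tr, "eclampsia", fired, record, "seizure_or_unresponsive")
  if (fired) return(cause_assignment(record, dtype, "eclampsia", tr, rs))

  fired <- ts_present(record$hemorrhage_gt_1000cc)
  tr <- trace_add(tr, "hemorrhage", fired, record, "hemorrhage_gt_1000cc")
  if (fired) return(cause_assignment(record, dtype, "hemorrhage", tr, rs))

  fired <- ts_present(record$maternal_infection_signs)
  tr <- trace_add(tr, "infection", fired, record, "maternal_infection_signs")
  if (fired) return(cause_assignment(record, dtype, "infection", tr, rs))

  fired <- ts_present(record$preeclampsia_signs)
  tr <- trace_add(tr, "preeclampsia_hypertensive", fired, record,
                  "preeclampsia_signs")
  if (fired) {
    return(cause_assignment(record, dtype, "preeclampsia_hypertensive",
                            tr, rs))
  }

  fired <- ts_present(record$acute_dyspnea_and_chest_pain)
  tr <- trace_add(tr, "thromboembolism", fired, record,
                  "acute_dyspnea_and_chest_pain")
  if (fired) return(cause_assignment(record, dtype, "thromboembolism", tr, rs))

  fired <- ts_present(record$medical_condition)
  tr <- trace_add(tr, "medical_condition", fired, record, "medical_condition")
  if (fired) return(cause_assignment(record, dtype, "medical_condition", tr, rs))

  tr <- trace_add(tr, "unknown", TRUE, record, character())
  cause_assignment(record, dtype, "unknown", tr, rs)
}
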