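# Convenience constructors for test case records, with triage
# defaults so each helper lands in the intended death type unless a
# test overrides them.

sb_rec <- function(..., id = "sb", ga = 38, bw = NA, sol = "absent",
                   macerated = "absent") {
  case_record(id, "fetus_or_neonate",
              gestational_age_weeks = ga, birth_weight_grams = bw,
              signs_of_life = sol, macerated = macerated, ...)
}

nn_rec <- function(..., id = "nn", ga = 39, bw = 3000, age = 1) {
  case_record(id, "fetus_or_neonate",
              gestational_age_weeks = ga, birth_weight_grams = bw,
              signs_of_life = "present", age_at_death_days = age, ...)
}

mat_rec <- function(..., id = "mat", weeks = 36) {
  case_record(id, "mother", pregnancy_weeks_at_death = weeks, ...)
}

cause_rank <- function(type, cause) match(cause, cause_labels(type))
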