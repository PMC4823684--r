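test_that("validate_record flags out-of-range numerics as errors", {
  r <- case_record("x", "fetus_or_neonate", gestational_age_weeks = 200)
  iss <- validate_record(r)
  expect_equal(sum(iss$severity == "error"), 1L)
  expect_match(iss$message[iss$severity == "error"], "gestational_age_weeks")

  r2 <- case_record("x", "fetus_or_neonate", temperature_celsius = 50,
                    birth_weight_grams = 50)
  iss2 <- validate_record(r2)
  expect_setequal(iss2$field[iss2$severity == "error"],
                  c("temperature_celsius", "birth_weight_grams"))
})

test_that("a fully populated well-formed record yields no issues", {
  r <- sb_rec(bw = 3100, maternal_trauma = "absent",
              fetal_trauma_signs = "absent",
              major_congenital_anomaly = "absent",
              maternal_infection_signs = "absent",
              cond_preeclampsia_eclampsia = "absent",
              cond_obstructed_or_prolonged_labor = "absent",
              cond_antepartum_hemorrhage = "absent",
              cond_fetal_distress = "absent",
              cond_cord_complication = "absent",
              cond_breech_presentation = "absent", cond_twins = "absent",
              hot_to_touch = "absent", cool_to_touch = "absent",
              seizures_ge_2_days = "absent",
              umbilical_discharge_pus_bleeding = "absent",
              pneumonia_signs = "absent",
              breathing_difficulty_or_no_cry = "absent",
              seizures_lt_2_days = "absent",
              resuscitation_at_birth = "absent",
              induced_abortion = "absent", ectopic_pregnancy = "absent",
              seizure_or_unresponsive = "absent",
              hemorrhage_gt_1000cc = "absent",
              preeclampsia_signs = "absent",
              acute_dyspnea_and_chest_pain = "absent",
              medical_condition = "absent")
  expect_equal(nrow(validate_record(r)), 0L)
})

test_that("an all-unknown record warns but is still classifiable, to unknown", {
  r <- case_record("x", "fetus_or_neonate", gestational_age_weeks = 38)
  iss <- validate_record(r)
  expect_true(nrow(iss) > 0)
  expect_true(all(iss$severity == "warning"))
  a <- classify_case(r)   # signs of life unknown -> conservative stillbirth
  expect_equal(a$death_type$kind, "stillbirth")
  expect_equal(a$death_type$stillbirth_timing, "indeterminate")
  expect_equal(a$cod_primary, "unknown")
  expect_true(any(a$rule_trace$unknown_inputs))
})

test_that("validation is pure: identical records give identical issue lists", {
  r1 <- sb_rec(macerated = "present", sol = "present")
  r2 <- sb_rec(macerated = "present", sol = "present")
  expect_identical(validate_record(r1), validate_record(r2))
  # contradiction is a warning, not an error
  iss <- validate_record(r1)
  expect_true("macerated" %in% iss$field[iss$severity == "warning"])
  expect_false(any(iss$severity == "error"))
})

test_that("the shipped column dictionary matches the in-code schema", {
  shipped <- system.file("extdata", "case_schema.csv", package = "codassign")
  on_disk <- utils::read.csv(shipped, stringsAsFactors = FALSE)
  expect_equal(on_disk$field, case_schema()$field)
  expect_equal(on_disk$type, case_schema()$type)
})
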