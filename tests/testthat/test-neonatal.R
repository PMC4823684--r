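rs <- default_ruleset()

test_that("neonatal hierarchy follows strict precedence", {
  # anencephaly with fever and breathing difficulty: anomaly wins
  a <- classify_neonatal(nn_rec(major_congenital_anomaly = "present",
                                hot_to_touch = "present",
                                breathing_difficulty_or_no_cry = "present"),
                         rs)
  expect_equal(a$cod_primary, "congenital_anomaly")
  # small preterm with respiratory distress: prematurity regardless
  a <- classify_neonatal(nn_rec(ga = 30, bw = 1200,
                                breathing_difficulty_or_no_cry = "present"),
                         rs)
  expect_equal(a$cod_primary, "complications_of_prematurity")
  # term infant, no cry, obstructed labor: asphyxia + associated condition
  a <- classify_neonatal(nn_rec(ga = 40,
                                breathing_difficulty_or_no_cry = "present",
                                cond_obstructed_or_prolonged_labor =
                                  "present"), rs)
  expect_equal(a$cod_primary, "asphyxia")
  expect_equal(a$cod_subtype, "obstructed_or_prolonged_labor")
  # late preterm with nothing found: prematurity, never unknown
  a <- classify_neonatal(nn_rec(ga = 35, bw = 2300), rs)
  expect_equal(a$cod_primary, "complications_of_prematurity")
  # term, all signs absent: unknown
  a <- classify_neonatal(nn_rec(ga = 40), rs)
  expect_equal(a$cod_primary, "unknown")
})

test_that("below 37 weeks, no anomaly/infection is never unknown", {
  cg <- classified_grid("neonatal", rs)
  g <- cg$grid
  sub <- g$gestational_age_weeks < 37 &
    g$major_congenital_anomaly == "absent" &
    g$hot_to_touch == "absent" & g$seizures_ge_2_days == "absent" &
    g$umbilical_discharge_pus_bleeding == "absent" &
    g$pneumonia_signs == "absent"
  expect_true(any(sub))
  expect_false(any(cg$asg$cod_primary[sub] == "unknown"))
  expect_true(all(cg$asg$cod_primary[sub] %in%
                  c("asphyxia", "complications_of_prematurity")))
})

test_that("small or early infants get prematurity unconditionally", {
  cg <- classified_grid("neonatal", rs)
  g <- cg$grid
  small <- (g$birth_weight_grams < 2000 | g$gestational_age_weeks < 34) &
    g$major_congenital_anomaly == "absent" &
    g$hot_to_touch == "absent" & g$seizures_ge_2_days == "absent" &
    g$umbilical_discharge_pus_bleeding == "absent" &
    g$pneumonia_signs == "absent"
  expect_true(all(cg$asg$cod_primary[small] ==
                  "complications_of_prematurity"))
  # discordant GA/BW corners: the prematurity branch wins
  expect_equal(classify_neonatal(nn_rec(ga = 35, bw = 1800,
    breathing_difficulty_or_no_cry = "present"), rs)$cod_primary,
    "complications_of_prematurity")
  expect_equal(classify_neonatal(nn_rec(ga = 33, bw = 2500,
    resuscitation_at_birth = "present"), rs)$cod_primary,
    "complications_of_prematurity")
})

test_that("classifier agrees with the lookup-table oracle on the full grid", {
  cg <- classified_grid("neonatal", rs)
  expect_equal(cg$asg$cod_primary, oracle_neonatal(cg$grid))
})

test_that("infection subtype precedence is tetanus > omphalitis > pneumonia > sepsis", {
  a <- classify_neonatal(nn_rec(seizures_ge_2_days = "present",
                                umbilical_discharge_pus_bleeding = "present",
                                hot_to_touch = "present"), rs)
  expect_equal(a$cod_primary, "infection")
  expect_equal(a$cod_subtype, "tetanus")
  expect_setequal(a$cod_subtypes_all, c("tetanus", "omphalitis", "sepsis"))
  a <- classify_neonatal(nn_rec(pneumonia_signs = "present",
                                cool_to_touch = "present"), rs)
  expect_equal(a$cod_subtype, "pneumonia")
})

test_that("measured temperature satisfies the fever/hypothermia criteria", {
  expect_equal(classify_neonatal(nn_rec(temperature_celsius = 38.2),
                                 rs)$cod_primary, "infection")
  expect_equal(classify_neonatal(nn_rec(temperature_celsius = 35.0),
                                 rs)$cod_primary, "infection")
  expect_equal(classify_neonatal(nn_rec(temperature_celsius = 36.8),
                                 rs)$cod_primary, "unknown")
})

test_that("seizure timing splits infection from asphyxia", {
  expect_equal(classify_neonatal(nn_rec(seizures_ge_2_days = "present"),
                                 rs)$cod_primary, "infection")
  expect_equal(classify_neonatal(nn_rec(seizures_lt_2_days = "present"),
                                 rs)$cod_primary, "asphyxia")
})

test_that("missing size fields fall back gracefully and are flagged", {
  # BW alone drives the split when GA is missing, and vice versa
  expect_equal(classify_neonatal(nn_rec(ga = NA, bw = 1500), rs)$cod_primary,
               "complications_of_prematurity")
  expect_equal(classify_neonatal(nn_rec(ga = 30, bw = NA), rs)$cod_primary,
               "complications_of_prematurity")
  # both missing: treated as term, trace flags the assumption
  a <- classify_neonatal(nn_rec(ga = NA, bw = NA), rs)
  expect_equal(a$cod_primary, "unknown")
  tr <- a$rule_trace
  expect_true(tr$unknown_inputs[tr$rule_id == "prematurity_small_or_early"])
})

test_that("classify_neonatal rejects records of other death types", {
  expect_error(classify_neonatal(sb_rec(), rs), "stillbirth")
})
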