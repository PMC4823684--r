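rs <- default_ruleset()

test_that("stillbirth hierarchy follows strict precedence", {
  # trauma beats everything, including co-occurring obstructed labor
  a <- classify_stillbirth(sb_rec(maternal_trauma = "present",
                                  cond_obstructed_or_prolonged_labor =
                                    "present"), rs)
  expect_equal(a$cod_primary, "trauma")
  # cord prolapse with nothing above it -> asphyxia, subtype recorded
  a <- classify_stillbirth(sb_rec(cond_cord_complication = "present"), rs)
  expect_equal(a$cod_primary, "asphyxia")
  expect_equal(a$cod_subtype, "cord_complication")
  # very preterm, not macerated, nothing else -> preterm labor
  a <- classify_stillbirth(sb_rec(ga = 28), rs)
  expect_equal(a$cod_primary, "complications_of_preterm_labor")
  # term, all signs absent -> unknown
  a <- classify_stillbirth(sb_rec(ga = 39,
                                  maternal_trauma = "absent",
                                  major_congenital_anomaly = "absent",
                                  maternal_infection_signs = "absent"), rs)
  expect_equal(a$cod_primary, "unknown")
})

test_that("preterm-labor rule needs maceration observed absent", {
  expect_equal(classify_stillbirth(sb_rec(ga = 28, macerated = "unknown"),
                                   rs)$cod_primary, "unknown")
  expect_equal(classify_stillbirth(sb_rec(ga = 28, macerated = "present"),
                                   rs)$cod_primary, "unknown")
  # birth weight alone can satisfy the size criterion
  expect_equal(classify_stillbirth(sb_rec(ga = 36, bw = 1400), rs)$cod_primary,
               "complications_of_preterm_labor")
})

test_that("asphyxia subtype tie-break is the fixed condition order", {
  a <- classify_stillbirth(sb_rec(cond_cord_complication = "present",
                                  cond_obstructed_or_prolonged_labor =
                                    "present",
                                  cond_fetal_distress = "present"), rs)
  expect_equal(a$cod_subtype, "obstructed_or_prolonged_labor")
  expect_setequal(a$cod_subtypes_all,
                  c("obstructed_or_prolonged_labor", "fetal_distress",
                    "cord_complication"))
})

test_that("classifier agrees with the lookup-table oracle on the full grid", {
  cg <- classified_grid("stillbirth", rs)
  expect_true(all(cg$asg$death_type == "stillbirth"))
  expect_equal(cg$asg$cod_primary, oracle_stillbirth(cg$grid))
})

test_that("setting a sign present never demotes the cause (monotonicity)", {
  flags <- grep("^(maternal_trauma|fetal_trauma_signs|major_congenital_anomaly|maternal_infection_signs|cond_)",
                case_schema()$field, value = TRUE)
  set.seed(101)
  for (i in 1:60) {
    vals <- sample(c("absent", "present", "unknown"), length(flags),
                   replace = TRUE, prob = c(0.6, 0.2, 0.2))
    args <- as.list(vals)
    names(args) <- flags
    r <- do.call(sb_rec, c(args, list(ga = sample(c(22, 30, 39), 1),
                                      macerated = sample(tristate_levels(), 1))))
    base <- cause_rank("stillbirth", classify_stillbirth(r, rs)$cod_primary)
    for (f in flags[vals == "absent"]) {
      r2 <- r
      r2[[f]] <- "present"
      flipped <- cause_rank("stillbirth",
                            classify_stillbirth(r2, rs)$cod_primary)
      expect_lte(flipped, base)
    }
  }
})

test_that("classify_stillbirth rejects records of other death types", {
  expect_error(classify_stillbirth(nn_rec(), rs), "neonatal_death")
  expect_error(classify_stillbirth(mat_rec(), rs), "maternal_death")
})

test_that("the rule trace is ordered and the first fired rule is the cause", {
  a <- classify_stillbirth(sb_rec(maternal_infection_signs = "present"), rs)
  fired <- a$rule_trace$rule_id[a$rule_trace$outcome == "fired"]
  expect_equal(fired[fired != "triage_stillbirth"][1], "infection")
  expect_equal(a$rule_trace$rule_id,
               c("triage_stillbirth", "trauma", "congenital_anomaly",
                 "infection"))
})
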