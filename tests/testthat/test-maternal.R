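rs <- default_ruleset()

test_that("maternal hierarchy follows strict precedence", {
  # under 20 weeks with hemorrhage and infection: abortion-related
  a <- classify_maternal(mat_rec(weeks = 18,
                                 hemorrhage_gt_1000cc = "present",
                                 maternal_infection_signs = "present"), rs)
  expect_equal(a$cod_primary, "abortion_related")
  # seizure beats hemorrhage at 36 weeks
  a <- classify_maternal(mat_rec(seizure_or_unresponsive = "present",
                                 hemorrhage_gt_1000cc = "present"), rs)
  expect_equal(a$cod_primary, "eclampsia")
  # preeclampsia without seizure yields to hemorrhage
  a <- classify_maternal(mat_rec(preeclampsia_signs = "present",
                                 hemorrhage_gt_1000cc = "present"), rs)
  expect_equal(a$cod_primary, "hemorrhage")
  # a lone medical condition
  a <- classify_maternal(mat_rec(medical_condition = "present"), rs)
  expect_equal(a$cod_primary, "medical_condition")
  # nothing found
  expect_equal(classify_maternal(mat_rec(), rs)$cod_primary, "unknown")
})

test_that("under 20 weeks without trauma is always abortion-related", {
  cg <- classified_grid("maternal", rs)
  g <- cg$grid
  sub <- !is.na(g$pregnancy_weeks_at_death) &
    g$pregnancy_weeks_at_death < 20 & g$maternal_trauma == "absent"
  expect_true(any(sub))
  expect_true(all(cg$asg$cod_primary[sub] == "abortion_related"))
  # but trauma still takes precedence below 20 weeks
  a <- classify_maternal(mat_rec(weeks = 12, maternal_trauma = "present"),
                         rs)
  expect_equal(a$cod_primary, "trauma")
})

test_that("ectopic pregnancy and induced abortion map to abortion-related", {
  expect_equal(classify_maternal(mat_rec(weeks = 8,
    ectopic_pregnancy = "present"), rs)$cod_primary, "abortion_related")
  # induced abortion at >= 20 weeks still counts
  expect_equal(classify_maternal(mat_rec(weeks = 24,
    induced_abortion = "present"), rs)$cod_primary, "abortion_related")
})

test_that("postpartum deaths skip the abortion rule unless it applied", {
  # pregnancy ended at term, death 2 weeks postpartum, hemorrhage
  r <- case_record("m", "mother", pregnancy_weeks_at_death = 39,
                   weeks_postpartum_at_death = 2,
                   hemorrhage_gt_1000cc = "present")
  expect_equal(classify_maternal(r, rs)$cod_primary, "hemorrhage")
  # pregnancy ended before 20 weeks, postpartum death: abortion-related
  r <- case_record("m", "mother", pregnancy_weeks_at_death = 16,
                   weeks_postpartum_at_death = 2,
                   hemorrhage_gt_1000cc = "present")
  expect_equal(classify_maternal(r, rs)$cod_primary, "abortion_related")
})

test_that("classifier agrees with the lookup-table oracle on the full grid", {
  cg <- classified_grid("maternal", rs)
  expect_true(all(cg$asg$death_type == "maternal_death"))
  expect_equal(cg$asg$cod_primary, oracle_maternal(cg$grid))
})

test_that("setting a sign present never demotes the cause (monotonicity)", {
  flags <- c("maternal_trauma", "induced_abortion", "ectopic_pregnancy",
             "seizure_or_unresponsive", "hemorrhage_gt_1000cc",
             "maternal_infection_signs", "preeclampsia_signs",
             "acute_dyspnea_and_chest_pain", "medical_condition")
  set.seed(202)
  for (i in 1:60) {
    vals <- sample(c("absent", "present", "unknown"), length(flags),
                   replace = TRUE, prob = c(0.6, 0.2, 0.2))
    args <- as.list(vals)
    names(args) <- flags
    r <- do.call(mat_rec, c(args, list(weeks = sample(c(12, 24, 39), 1))))
    base <- cause_rank("maternal", classify_maternal(r, rs)$cod_primary)
    for (f in flags[vals == "absent"]) {
      r2 <- r
      r2[[f]] <- "present"
      expect_lte(cause_rank("maternal",
                            classify_maternal(r2, rs)$cod_primary), base)
    }
  }
})

test_that("classify_maternal rejects records of other death types", {
  expect_error(classify_maternal(sb_rec(), rs), "stillbirth")
})
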