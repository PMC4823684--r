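# Independent lookup-table oracles, coded straight from the published
# cause tables (row order = precedence) as vectorized truth tables
# over grid data.frames. They never call the package's classifiers:
# agreement between the two routes is what the exhaustive-grid tests
# establish.

oracle_stillbirth <- function(g, preterm_weeks = 32, preterm_grams = 1500) {
  p <- function(col) !is.na(g[[col]]) & g[[col]] == "present"
  ga <- g$gestational_age_weeks
  bw <- g$birth_weight_grams
  trauma <- p("maternal_trauma") | p("fetal_trauma_signs")
  anomaly <- p("major_congenital_anomaly")
  infection <- p("maternal_infection_signs")
  asphyxia <- p("cond_preeclampsia_eclampsia") |
    p("cond_obstructed_or_prolonged_labor") |
    p("cond_antepartum_hemorrhage") | p("cond_fetal_distress") |
    p("cond_cord_complication")
  small <- (!is.na(ga) & ga < preterm_weeks) |
           (!is.na(bw) & bw < preterm_grams)
  preterm <- small & !is.na(g$macerated) & g$macerated == "absent"
  ifelse(trauma, "trauma",
  ifelse(anomaly, "congenital_anomaly",
  ifelse(infection, "infection",
  ifelse(asphyxia, "asphyxia",
  ifelse(preterm, "complications_of_preterm_labor", "unknown")))))
}

oracle_neonatal <- function(g, prem_weeks = 34, prem_grams = 2000,
                            term_weeks = 37) {
  p <- function(col) !is.na(g[[col]]) & g[[col]] == "present"
  ga <- g$gestational_age_weeks
  bw <- g$birth_weight_grams
  anomaly <- p("major_congenital_anomaly")
  infection <- p("hot_to_touch") | p("seizures_ge_2_days") |
    p("umbilical_discharge_pus_bleeding") | p("pneumonia_signs")
  small <- (!is.na(bw) & bw < prem_grams) | (!is.na(ga) & ga < prem_weeks)
  asphyxia <- p("breathing_difficulty_or_no_cry") |
    p("seizures_lt_2_days") | p("resuscitation_at_birth")
  late_preterm <- !is.na(ga) & ga < term_weeks
  ifelse(anomaly, "congenital_anomaly",
  ifelse(infection, "infection",
  ifelse(small, "complications_of_prematurity",
  ifelse(asphyxia, "asphyxia",
  ifelse(late_preterm, "complications_of_prematurity", "unknown")))))
}

oracle_maternal <- function(g, abortion_weeks = 20) {
  p <- function(col) !is.na(g[[col]]) & g[[col]] == "present"
  wk <- g$pregnancy_weeks_at_death
  abortion <- (!is.na(wk) & wk < abortion_weeks) | p("ectopic_pregnancy") |
    p("induced_abortion")
  ifelse(p("maternal_trauma"), "trauma",
  ifelse(abortion, "abortion_related",
  ifelse(p("seizure_or_unresponsive"), "eclampsia",
  ifelse(p("hemorrhage_gt_1000cc"), "hemorrhage",
  ifelse(p("maternal_infection_signs"), "infection",
  ifelse(p("preeclampsia_signs"), "preeclampsia_hypertensive",
  ifelse(p("acute_dyspnea_and_chest_pain"), "thromboembolism",
  ifelse(p("medical_condition"), "medical_condition", "unknown"))))))))
}

# Full enumeration grids used by several test files; classified once
# per session and cached.
.grid_cache <- new.env(parent = emptyenv())

full_grid <- function(type) {
  switch(type,
    stillbirth = enumerate_grid("stillbirth",
                                ga_values = c(22, 28, 31, 32, 36, 40)),
    neonatal = enumerate_grid("neonatal",
                              ga_values = c(28, 33, 34, 36, 37, 41),
                              bw_values = c(1500, 1999, 2000, 2500, 3200)),
    maternal = enumerate_grid("maternal",
                              ga_values = c("8", "19", "20", "28", "40",
                                            "postpartum"))
  )
}

classified_grid <- function(type, rs = default_ruleset()) {
  key <- paste(type, rs$version, sep = "|")
  if (is.null(.grid_cache[[key]])) {
    g <- full_grid(type)
    .grid_cache[[key]] <- list(grid = g,
                               asg = classify_batch(g, rs, trace = FALSE))
  }
  .grid_cache[[key]]
}
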