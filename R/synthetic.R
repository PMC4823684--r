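# Binary sign flags enumerated per death type. Stillbirth grids are
# additionally crossed with maceration (3 levels) because the
# preterm-labor rule and the timing call both hinge on it.
grid_flags <- function(death_type) {
  switch(death_type,
    stillbirth = c("maternal_trauma", "fetal_trauma_signs",
                   "major_congenital_anomaly", "maternal_infection_signs",
                   paste0("cond_", stillbirth_asphyxia_conditions())),
    neonatal = c("major_congenital_anomaly", "hot_to_touch",
                 "seizures_ge_2_days", "umbilical_discharge_pus_bleeding",
                 "pneumonia_signs", "breathing_difficulty_or_no_cry",
                 "seizures_lt_2_days", "resuscitation_at_birth"),
    maternal = c("maternal_trauma", "induced_abortion", "ectopic_pregnancy",
                 "seizure_or_unresponsive", "hemorrhage_gt_1000cc",
                 "maternal_infection_signs", "preeclampsia_signs",
                 "acute_dyspnea_and_chest_pain", "medical_condition"),
    stop("unknown death_type: ", death_type, call. = FALSE)
  )
}

#' Enumerate an exhaustive grid of synthetic case records
#'
#' Yields every combination of the binary sign flags relevant to one
#' death type, crossed with the supplied gestational-age and
#' birth-weight values (stillbirth grids are also crossed with the
#' three maceration states). The ordering is deterministic, so the
#' grid doubles as a reproducible exhaustive test bed: an
#' independently coded oracle can be compared with the classifier on
#' every cell.
#'
#' @param death_type `"stillbirth"`, `"neonatal"` or `"maternal"`.
#' @param ga_values gestational ages in completed weeks (for maternal
#'   grids: pregnancy weeks at death; the string `"postpartum"` adds
#'   a postpartum stratum at 39 weeks gestation, 2 weeks postpartum).
#'   `NA` means missing.
#' @param bw_values birth weights in grams (`NA` = missing); ignored
#'   for maternal grids.
#' @param max_cases refuse to materialize grids larger than this
#'   (default 100000); the error reports the computed size.
#' @return data.frame of raw case columns (one row per grid cell)
#'   ready for [classify_batch()], with the grid's flag columns set
#'   to `present`/`absent` and everything else at its default.
#' @export
#' @examples
#' g <- enumerate_grid("neonatal", ga_values = c(33, 40),
#'                     bw_values = c(1800, 3000))
#' nrow(g)  # 2^8 flags x 2 GA x 2 BW = 1024
enumerate_grid <- function(death_type,
                           ga_values,
                           bw_values = NA_real_,
                           max_cases = 100000) {
  death_type <- match.arg(death_type, c("stillbirth", "neonatal", "maternal"))
  if (length(ga_values) == 0L) stop("ga_values must be non-empty", call. = FALSE)
  if (length(bw_values) == 0L) stop("bw_values must be non-empty", call. = FALSE)
  flags <- grid_flags(death_type)
  levs <- rep(list(c("absent", "present")), length(flags))
  names(levs) <- flags
  if (death_type == "stillbirth") {
    levs$macerated <- c("present", "absent", "unknown")
  }
  if (death_type == "maternal") {
    levs$.wk <- as.character(ga_values)
    bw_values <- NA_real_
  } else {
    levs$.ga <- as.character(ga_values)
    levs$.bw <- as.character(bw_values)
  }
  size <- prod(vapply(levs, length, 0L))
  if (size > max_cases) {
    stop("grid size ", size, " exceeds max_cases = ", max_cases,
         call. = FALSE)
  }
  g <- expand.grid(levs, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(g)
  out <- data.frame(case_id = sprintf("grid-%06d", seq_len(n)),
                    stringsAsFactors = FALSE)
  if (death_type == "maternal") {
    out$subject_kind <- "mother"
    wk <- g$.wk
    out$pregnancy_weeks_at_death <-
      ifelse(wk == "postpartum", 39, suppressWarnings(as.numeric(wk)))
    out$weeks_postpartum_at_death <- ifelse(wk == "postpartum", 2, NA_real_)
  } else {
    out$subject_kind <- "fetus_or_neonate"
    out$gestational_age_weeks <- suppressWarnings(as.numeric(g$.ga))
    out$birth_weight_grams <- suppressWarnings(as.numeric(g$.bw))
    if (death_type == "stillbirth") {
      out$signs_of_life <- "absent"
      out$macerated <- g$macerated
    } else {
      out$signs_of_life <- "present"
      out$age_at_death_days <- 1
    }
  }
  for (f in flags) out[[f]] <- g[[f]]
  out
}

#' Specify a stochastic synthetic cohort
#'
#' Describes a cohort of synthetic deaths: its size, the mix of death
#' types, the cause mix within each death type, how often extraneous
#' lower-priority signs are added (`noise_rate`), and how often
#' non-defining sign fields are masked to unknown
#' (`missingness_rate`). Because noise only ever adds signs of lower
#' precedence than the generating cause, and unknown signs are inert
#' when the hierarchy descends, a generated case always classifies to
#' its generating (`true_cause`) label -- which is what makes the
#' cohort a recovery benchmark rather than a realism claim.
#'
#' @param n_cases positive integer.
#' @param death_type_mix named fractions over `stillbirth`,
#'   `neonatal`, `maternal`, summing to 1.
#' @param cause_mix named list (one element per death type present in
#'   `death_type_mix`) of named fractions over that type's cause
#'   labels (see [cause_labels()]), each summing to 1. Defaults to a
#'   mix typical of low-resource cohort reports.
#' @param missingness_rate,noise_rate fractions in `[0, 1]`.
#' @param seed integer seed; generation is fully reproducible.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec(100, seed = 7)
cohort_spec <- function(n_cases,
                        death_type_mix = c(stillbirth = 0.45,
                                           neonatal = 0.45,
                                           maternal = 0.10),
                        cause_mix = default_cause_mix(),
                        missingness_rate = 0,
                        noise_rate = 0,
                        seed = 1) {
  stopifnot(is.numeric(n_cases), length(n_cases) == 1L, n_cases >= 1)
  check_mix <- function(m, allowed, what) {
    if (is.null(names(m)) || any(!nzchar(names(m)))) {
      stop(what, " must be a named fraction vector", call. = FALSE)
    }
    bad <- setdiff(names(m), allowed)
    if (length(bad) > 0L) {
      stop(what, " names unknown: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
      stop(what, " fractions must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  check_mix(death_type_mix, c("stillbirth", "neonatal", "maternal"),
            "death_type_mix")
  for (dt in names(death_type_mix)[death_type_mix > 0]) {
    if (is.null(cause_mix[[dt]])) {
      stop("cause_mix missing entry for death type '", dt, "'",
           call. = FALSE)
    }
    check_mix(cause_mix[[dt]], cause_labels(dt),
              paste0("cause_mix$", dt))
  }
  for (r in c(missingness_rate, noise_rate)) {
    stopifnot(is.numeric(r), length(r) == 1L, r >= 0, r <= 1)
  }
  structure(list(n_cases = as.integer(n_cases),
                 death_type_mix = death_type_mix,
                 cause_mix = cause_mix,
                 missingness_rate = missingness_rate,
                 noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cause_mix <- function() {
  list(
    stillbirth = c(trauma = 0.02, congenital_anomaly = 0.05,
                   infection = 0.13, asphyxia = 0.45,
                   complications_of_preterm_labor = 0.15, unknown = 0.20),
    neonatal = c(congenital_anomaly = 0.05, infection = 0.30,
                 asphyxia = 0.30, complications_of_prematurity = 0.30,
                 unknown = 0.05),
    maternal = c(trauma = 0.05, abortion_related = 0.10, eclampsia = 0.15,
                 hemorrhage = 0.30, infection = 0.15,
                 preeclampsia_hypertensive = 0.10, thromboembolism = 0.05,
                 medical_condition = 0.05, unknown = 0.05)
  )
}

# Archetype for one (death_type, cause): the defining sign(s) present,
# all higher-priority signs absent. Returns list(fields = overrides,
# protected = sign fields missingness must not touch, rank = the
# cause's position in its hierarchy).
synth_archetype <- function(death_type, cause) {
  ga_term <- sample(37:41, 1L)
  bw_term <- sample(seq(2500, 4000, by = 50), 1L)
  if (death_type == "stillbirth") {
    f <- list(subject_kind = "fetus_or_neonate", signs_of_life = "absent",
              macerated = "absent", gestational_age_weeks = ga_term,
              birth_weight_grams = bw_term)
    prot <- "signs_of_life"
    rank <- match(cause, cause_labels("stillbirth"))
    if (cause == "trauma") {
      f$maternal_trauma <- "present"; prot <- c(prot, "maternal_trauma")
    } else if (cause == "congenital_anomaly") {
      f$major_congenital_anomaly <- "present"
      prot <- c(prot, "major_congenital_anomaly")
    } else if (cause == "infection") {
      f$maternal_infection_signs <- "present"
      prot <- c(prot, "maternal_infection_signs")
    } else if (cause == "asphyxia") {
      cond <- paste0("cond_", sample(stillbirth_asphyxia_conditions(), 1L))
      f[[cond]] <- "present"; prot <- c(prot, cond)
    } else if (cause == "complications_of_preterm_labor") {
      f$gestational_age_weeks <- sample(22:31, 1L)
      f$birth_weight_grams <- sample(seq(500, 1450, by = 50), 1L)
      prot <- c(prot, "macerated")   # "not macerated" is load-bearing
    }
    return(list(fields = f, protected = prot, rank = rank))
  }
  if (death_type == "neonatal") {
    f <- list(subject_kind = "fetus_or_neonate", signs_of_life = "present",
              age_at_death_days = sample(0:27, 1L),
              gestational_age_weeks = ga_term, birth_weight_grams = bw_term)
    prot <- "signs_of_life"
    rank <- match(cause, cause_labels("neonatal"))
    if (cause == "congenital_anomaly") {
      f$major_congenital_anomaly <- "present"
      prot <- c(prot, "major_congenital_anomaly")
    } else if (cause == "infection") {
      sig <- sample(c("hot_to_touch", "seizures_ge_2_days",
                      "umbilical_discharge_pus_bleeding",
                      "pneumonia_signs"), 1L)
      f[[sig]] <- "present"; prot <- c(prot, sig)
    } else if (cause == "asphyxia") {
      sig <- sample(c("breathing_difficulty_or_no_cry", "seizures_lt_2_days",
                      "resuscitation_at_birth"), 1L)
      f[[sig]] <- "present"; prot <- c(prot, sig)
      if (stats::runif(1) < 0.5) {
        cond <- paste0("cond_", sample(neonatal_asphyxia_conditions(), 1L))
        f[[cond]] <- "present"
      }
    } else if (cause == "complications_of_prematurity") {
      f$gestational_age_weeks <- sample(26:33, 1L)
      f$birth_weight_grams <- sample(seq(700, 1950, by = 50), 1L)
    }
    return(list(fields = f, protected = prot, rank = rank))
  }
  # maternal
  f <- list(subject_kind = "mother",
            pregnancy_weeks_at_death = sample(21:40, 1L))
  prot <- character()
  rank <- match(cause, cause_labels("maternal"))
  sign_for <- c(trauma = "maternal_trauma",
                eclampsia = "seizure_or_unresponsive",
                hemorrhage = "hemorrhage_gt_1000cc",
                infection = "maternal_infection_signs",
                preeclampsia_hypertensive = "preeclampsia_signs",
                thromboembolism = "acute_dyspnea_and_chest_pain",
                medical_condition = "medical_condition")
  if (cause == "abortion_related") {
    mode <- sample(c("early", "ectopic", "induced"), 1L,
                   prob = c(0.6, 0.2, 0.2))
    if (mode == "early") {
      f$pregnancy_weeks_at_death <- sample(6:19, 1L)
    } else if (mode == "ectopic") {
      f$pregnancy_weeks_at_death <- sample(6:12, 1L)
      f$ectopic_pregnancy <- "present"
      prot <- c(prot, "ectopic_pregnancy")
    } else {
      f$induced_abortion <- "present"
      prot <- c(prot, "induced_abortion")
    }
  } else if (cause != "unknown") {
    sig <- sign_for[[cause]]
    f[[sig]] <- "present"
    prot <- c(prot, sig)
  }
  list(fields = f, protected = prot, rank = rank)
}

# Signs that only influence rules of the given rank or lower (i.e.
# strictly lower-priority than the generating cause): the pool the
# noise process may add from without changing the true cause.
lower_priority_signs <- function(death_type, rank) {
  ranked <- switch(death_type,
    stillbirth = list(
      `1` = c("maternal_trauma", "fetal_trauma_signs"),
      `2` = "major_congenital_anomaly",
      `3` = "maternal_infection_signs",
      `4` = paste0("cond_", stillbirth_asphyxia_conditions())),
    neonatal = list(
      `1` = "major_congenital_anomaly",
      `2` = c("hot_to_touch", "seizures_ge_2_days",
              "umbilical_discharge_pus_bleeding", "pneumonia_signs"),
      `4` = c("breathing_difficulty_or_no_cry", "seizures_lt_2_days",
              "resuscitation_at_birth")),
    maternal = list(
      `1` = "maternal_trauma",
      `2` = c("ectopic_pregnancy", "induced_abortion"),
      `3` = "seizure_or_unresponsive",
      `4` = "hemorrhage_gt_1000cc",
      `5` = "maternal_infection_signs",
      `6` = "preeclampsia_signs",
      `7` = "acute_dyspnea_and_chest_pain",
      `8` = "medical_condition")
  )
  ranks <- as.integer(names(ranked))
  unlist(ranked[ranks > rank], use.names = FALSE)
}

#' Sample a stochastic synthetic cohort
#'
#' Draws each case's death type and true cause from the cohort spec's mixes,
#' emits the sign pattern that the hierarchy maps to that cause (the
#' defining sign present, all higher-priority signs absent), then
#' adds lower-priority noise signs with probability `noise_rate` each
#' and masks non-defining tri-state sign fields to unknown with
#' probability `missingness_rate` each. Fully reproducible from
#' `spec$seed`; the caller's RNG state is left untouched.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of raw case columns plus `true_death_type` and
#'   `true_cause` label columns, suitable for [classify_batch()]
#'   (which ignores the two label columns).
#' @export
#' @examples
#' co <- sample_cohort(cohort_spec(50, seed = 42))
#' table(co$true_death_type)
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(spec$seed)
  n <- spec$n_cases
  dtm <- spec$death_type_mix
  types <- sample(names(dtm), n, replace = TRUE, prob = dtm)
  sc <- case_schema()
  tri_fields <- schema_tristate_fields()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dt <- types[i]
    cm <- spec$cause_mix[[dt]]
    cause <- sample(names(cm), 1L, prob = cm)
    arch <- synth_archetype(dt, cause)
    f <- arch$fields
    # start from the all-absent sign baseline
    rec <- stats::setNames(vector("list", nrow(sc)), sc$field)
    for (k in seq_len(nrow(sc))) {
      rec[[k]] <- if (sc$type[k] == "tristate") "absent" else NA_real_
    }
    rec$case_id <- sprintf("synth-%06d", i)
    rec[names(f)] <- f
    # noise: extraneous strictly-lower-priority signs
    if (spec$noise_rate > 0) {
      for (s in lower_priority_signs(dt, arch$rank)) {
        if (stats::runif(1) < spec$noise_rate) rec[[s]] <- "present"
      }
    }
    # missingness: mask non-defining tri-state fields to unknown
    if (spec$missingness_rate > 0) {
      maskable <- setdiff(tri_fields, c(arch$protected,
                                        names(f)[vapply(f, identical, TRUE,
                                                        "present")]))
      for (s in maskable) {
        if (stats::runif(1) < spec$missingness_rate) rec[[s]] <- "unknown"
      }
    }
    rec$true_death_type <- dt
    rec$true_cause <- cause
    rows[[i]] <- rec
  }
  fields <- c(sc$field, "true_death_type", "true_cause")
  out <- stats::setNames(
    lapply(fields, function(f) {
      vals <- lapply(rows, `[[`, f)
      vals[vapply(vals, is.null, TRUE)] <- NA
      unlist(vals, use.names = FALSE)
    }),
    fields)
  as.data.frame(out, stringsAsFactors = FALSE)
}
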