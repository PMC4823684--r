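# codassign

Deterministic, auditable assignment of a single primary cause of death for
stillbirths, neonatal deaths and maternal deaths from minimal,
field-collectable data.

## The problem

In low-resource settings, where the overwhelming majority of
pregnancy-related deaths occur, autopsy, placental histology, imaging and
cultures are rarely available, and verbal-autopsy interviews are too
burdensome to run population-wide. When clinicians assign causes by
judgement, the same case data yield different causes from different
classifiers, so cause-specific mortality cannot be compared across sites
or over time. `codassign` implements a rules engine for exactly this
setting: a small set of observable data elements (gestational age, birth
weight, signs of life at delivery, maceration, and yes/no clinical sign
flags a family member or lay health worker can report) is fed through a
fixed hierarchy of causes, and the *algorithm* — never a person — assigns
one primary cause, compatible with ICD-10 top-level categories.

## The algorithm

Every case is first **triaged**:

* mothers → maternal death (through 6 weeks postpartum);
* fetus/neonate under 20 completed weeks gestation (or under 500 g when
  gestational age is unavailable) → miscarriage/abortion, outside the
  system;
* signs of life at delivery (heartbeat, cry, breathing, movement) and
  death before 28 days → neonatal death;
* no signs of life at ≥20 weeks → stillbirth, with maceration marking the
  death as antepartum (>12 h before delivery) versus
  intrapartum-or-recent.

Each death type then descends a strict precedence hierarchy; the first
rule that fires is the cause:

| rank | stillbirth | neonatal death | maternal death |
|------|------------|----------------|----------------|
| 1 | trauma | congenital anomaly | trauma |
| 2 | congenital anomaly | infection (tetanus/omphalitis/pneumonia/sepsis) | abortion-related (<20 wk, ectopic, induced) |
| 3 | maternal infection | prematurity (<2000 g or <34 wk, unconditional) | eclampsia (seizure) |
| 4 | asphyxia (associated maternal/fetal condition) | asphyxia (breathing difficulty / no cry, early seizures, resuscitation) | hemorrhage (>1000 cc) |
| 5 | preterm labor (<32 wk or <1500 g, not macerated) | prematurity (34–36 wk) | infection |
| 6 | unknown | unknown (term only) | preeclampsia without seizure |
| 7 | | | thromboembolism |
| 8 | | | coincident medical condition |
| 9 | | | unknown |

Signs are tri-state (`present` / `absent` / `unknown`); unknown is
treated as absent when the hierarchy descends, and every assignment
carries an ordered **rule trace** that records which rules were
evaluated, which inputs they used, and which decisions rested on unknown
inputs. All thresholds live in a versioned, configurable **ruleset**
(YAML/JSON), and the version is stamped into every assignment so cohorts
can be reclassified later under a revised ruleset.

## Worked example

```r
library(codassign)
rs <- default_ruleset()
r <- case_record("case-042", "mother",
                 pregnancy_weeks_at_death = 36,
                 seizure_or_unresponsive = "yes",
                 hemorrhage_gt_1000cc = "yes",
                 preeclampsia_signs = "yes")
classify_case(r, rs)
#> <cause_assignment> case-042
#>   death_type:      maternal_death
#>   cod_primary:     eclampsia
#>   ruleset:         gn-1.0
#>   rule trace:
#>     triage_maternal    fired     pregnancy_weeks_at_death=36; weeks_postpartum_at_death=missing  [unknown inputs]
#>     trauma             not_fired maternal_trauma=unknown  [unknown inputs]
#>     abortion_related   not_fired pregnancy_weeks_at_death=36; ectopic_pregnancy=unknown; induced_abortion=unknown  [unknown inputs]
#>     eclampsia          fired     seizure_or_unresponsive=present
```

The woman had hemorrhage and preeclampsia signs as well, but the seizure
promotes the death to eclampsia, which outranks both: one primary cause,
and the trace shows why — including that no trauma information was
recorded (treated as absent, flagged as unknown).

Batch use with the synthetic cohort generator:

```r
co <- sample_cohort(cohort_spec(1000, seed = 1))
summarize_cohort(classify_batch(co, rs))
#> <cohort_summary> 1000 assignment(s)
#>   stillbirth (n = 431)
#>     trauma                                7     1.6%
#>     congenital_anomaly                   22     5.1%
#>     infection                            64    14.8%
#>     asphyxia                            187    43.4%
#>     complications_of_preterm_labor       65    15.1%
#>     unknown                              86    20.0%
#>   neonatal_death (n = 459)
#>     ...
#>   maternal_death (n = 110)
#>     ...
```

With noise and missingness at zero, every assignment equals the
generating cause; the fractions estimate the generator's cause mix.

Command line (CSV or JSON-lines in and out):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "codassign.R", package = "codassign"))')
Rscript "$CLI" simulate --n 1000 --seed 1 --output cohort.csv
Rscript "$CLI" classify --input cohort.csv --output assigned.csv
Rscript "$CLI" summarize --input assigned.csv
```

## Scope and caveats

The system deliberately uses no autopsy, placental, laboratory or
imaging findings, assigns exactly one primary cause (no
secondary/contributing causes), and leaves deaths outside its
definitions (miscarriage before 20 weeks, live-born deaths at ≥28 days,
maternal deaths beyond 6 weeks postpartum) as explicitly
not-classifiable rather than forcing them into a category. See the
methods vignette (`vignettes/cause-assignment.Rmd`) for the full model
description, parameter meanings, synthetic-generator assumptions and
known limitations.
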