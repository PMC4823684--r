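---
title: "Hierarchical cause-of-death assignment: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical cause-of-death assignment: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codassign)
```

## The model

`codassign` is a single-cause, hierarchical classification system for
pregnancy-related deaths in settings where only minimal observational
data exist. Its two core commitments are:

1. **Minimal inputs.** Every data element is something a mother, family
   member or lay health worker can report, or that needs only basic
   equipment (a scale, a thermometer, a blood-pressure cuff). There are
   no autopsy, placental, culture or imaging inputs.
2. **Algorithmic assignment.** Once the signs are recorded, no human
   judgement enters the cause assignment. Identical inputs always yield
   identical outputs, which is what makes cause-specific mortality
   fractions comparable across sites and over time.

The price of these commitments is coarseness: the system assigns one
primary cause from a short, closed list per death type, and rare or
subtle causes are folded into broader categories or end up `unknown`.
That trade is deliberate: reproducibility and population-level
comparability are the goals, not case-level diagnostic nuance.

### Triage

A record is first routed to a death type. For a fetus or neonate the
stillbirth-versus-miscarriage boundary is 20 completed weeks of
gestation; birth weight (500 g) is consulted **only when gestational
age is missing** — when both are present and discordant, gestational age
wins. We read "lower limit" as inclusive: exactly 20.0 weeks or exactly
500 g qualifies. Signs of life at delivery (any of heartbeat, cry,
breathing, movement, pooled with the tri-state disjunction
`tristate_any()`) separate neonatal deaths (death before 28 days) from
stillbirths; when signs of life were not observed at ≥20 weeks we triage
conservatively to stillbirth, matching field practice, and the rule
trace flags the uncertainty. A live-born infant whose age at death is
missing is *not* assumed neonatal — the record returns
`not_classifiable` with a reason, because silently assuming the neonatal
window would fabricate the one fact the window depends on.

Stillbirth timing rests on maceration alone: maceration implies the
fetus died more than ~12 hours before delivery (antepartum); its
observed absence implies death in or near labor; unknown gives
`indeterminate`. Timing never influences the cause (except through the
preterm-labor rule below, which uses maceration directly).

### The three hierarchies

Within each death type, candidate causes are tested in a fixed
precedence order and the first match wins. The orders are a modeling
assumption about which observed condition is most informative about the
death, not a claim about mechanism — e.g. an anencephalic infant who
also has fever died *with* an infection but *of* the anomaly.

Two points where the source material needed interpretation:

* **Neonatal size split.** The "larger/late-preterm" (≥2000 g or ≥34
  weeks) and "small/early" (<2000 g or <34 weeks) branches are not
  mutually exclusive when weight and gestational age disagree (35
  weeks, 1800 g satisfies both). We evaluate the small/early branch
  first and let it win: prematurity is meant to be unconditional for
  small infants regardless of respiratory distress, so a 1800-g
  35-weeker with breathing difficulty is `complications_of_prematurity`,
  not asphyxia. The exhaustive-grid tests cover the discordant corners.
* **Maternal hierarchy order.** Narrative descriptions of the maternal
  algorithm place eclampsia before hemorrhage before infection; a
  summary-table rendering lists infection first. We implement the
  narrative/flow-chart order (trauma → abortion → eclampsia →
  hemorrhage → infection → preeclampsia → thromboembolism → medical →
  unknown), because it is the step-by-step algorithm. The hierarchy
  *order* is fixed in code rather than made configurable: unlike a
  numeric threshold, reordering rules changes the identity of the
  algorithm, and a config file that could silently permute the
  hierarchy would undermine the system's comparability promise.
  Numeric thresholds, by contrast, are all ruleset fields.

Other fixed interpretive choices, each covered by tests:

* The stillbirth preterm-labor rule (<32 weeks or <1500 g) requires
  maceration to be **observed absent**, not merely not-present: the
  rule's rationale is that the fetus died *in labor*, and an
  unexamined fetus gives no evidence of that. With maceration unknown
  the record falls through to `unknown`.
* Stillbirth asphyxia conditions are preeclampsia/eclampsia, obstructed
  or prolonged labor, antepartum hemorrhage, fetal distress, and cord
  complications. Breech presentation and twins enter only as
  asphyxia-*associated* conditions on the neonatal side. Intrauterine
  growth restriction, which appears in narrative lists but not in the
  operational definitions, is excluded from the default condition set.
* When several asphyxia conditions co-occur, all are recorded in
  `cod_subtypes_all` and the first in the fixed order above becomes the
  primary subtype. The order is a determinism device, not an
  epidemiological ranking.
* Neonatal seizure timing: seizures starting at ≥2 days of age point to
  infection; seizures within 2 days of birth point to asphyxia. Day 2
  exactly goes to infection, reading the "≥2 days" criterion literally.
* Neonatal infection subtypes are derived from the recorded signs with
  precedence tetanus > omphalitis > pneumonia > sepsis. The record
  schema has no tetanus-specific field; we map late seizures (≥2 days)
  to tetanus because that is the classic field presentation of neonatal
  tetanus and it is the only late-seizure sign in the schema. Umbilical
  pus/discharge maps to omphalitis, pneumonia signs to pneumonia, and
  fever/hypothermia alone to sepsis. All present subtypes are reported.
* Resuscitation at birth counts as an asphyxia sign even without
  recorded breathing difficulty, including in 34--36-week infants ≥2000
  g; it is listed among the asphyxia signs and a resuscitation attempt
  is direct evidence of compromise at birth.
* Maternal deaths: ectopic pregnancy is abortion-related at any
  gestation; standalone severe anemia is a coincident medical
  condition (it also appears as a hemorrhage qualifier in the source
  definitions — when hemorrhage itself is recorded, hemorrhage fires
  first anyway). Postpartum deaths use the gestation at which the
  pregnancy *ended*, so a term delivery followed by postpartum
  hemorrhage is `hemorrhage`, while a pregnancy lost at 16 weeks
  remains abortion-related even if the death came days later.
* Obstructed labor and ruptured uterus are never maternal causes;
  those deaths surface as the infection or hemorrhage they produce.
  Obstructed labor can still appear as the *associated condition* of a
  fetal/neonatal asphyxia.

### Missing data

The source system assumes signs are either noted or not; it does not
say what to do with explicit missingness. Our convention, applied
uniformly: every sign is tri-state, and **unknown is treated as absent
when the hierarchy descends**, so every record receives an assignment
(totality). The cost — an unobserved high-priority sign lets a
lower-priority cause fire — is made auditable rather than hidden: each
trace row carries an `unknown_inputs` flag, the batch output counts
rules decided on unknown inputs, and `validate_record()` warns when more
than half of a record's sign fields are unknown. `unknown` the *cause*
is therefore reachable in two ways (all relevant signs observed absent,
or nothing observed), and the trace distinguishes them.

## Parameters

All thresholds live in the versioned ruleset (`default_ruleset()`):

| field | default | units | role |
|---|---|---|---|
| `stillbirth_min_weeks` / `stillbirth_min_grams` | 20 / 500 | weeks / g | miscarriage boundary (weight is GA fallback) |
| `maceration_hours_implies_antepartum` | 12 | h | documented meaning of maceration |
| `neonatal_period_days` | 28 | days | neonatal death window |
| `term_weeks` | 37 | weeks | below: never-unknown rule |
| `neonatal_prematurity_weeks` / `_grams` | 34 / 2000 | weeks / g | unconditional-prematurity branch |
| `stillbirth_preterm_weeks` / `_grams` | 32 / 1500 | weeks / g | stillbirth preterm-labor rule |
| `fever_celsius` / `hypothermia_celsius` | 37.5 / 35.5 | °C | neonatal infection criteria |
| `bradycardia_bpm` / `tachycardia_bpm` | 120 / 160 | bpm | fetal-distress definition (documentation; distress is a recorded sign) |
| `hemorrhage_cc` | 1000 | cc | hemorrhage definition |
| `maternal_abortion_weeks` | 20 | weeks | abortion-related override |
| `maternal_postpartum_weeks` | 6 | weeks | maternal-death window |

Temperature is accepted both as a measured number and as touch-based
flags (`hot_to_touch`, `cool_to_touch`); either satisfies the
fever/hypothermia criterion, because a thermometer cannot be assumed.
Units are fixed (completed weeks, grams, days, °C, cc) and the readers
never convert silently. The numeric validation bounds (gestational age
4–50 weeks, birth weight 100–8000 g, temperature 25–45 °C) are
data-entry sanity limits of our own choosing, not clinical thresholds.

## The synthetic generator

No public case-level data exist for this record schema, so the package
carries its own generator with two modes.

**Exhaustive grids** (`enumerate_grid()`) cross every combination of
the binary sign flags relevant to one death type with chosen
gestational-age/birth-weight values (and, for stillbirths, the three
maceration states). These are the test bed on which the classifiers are
compared cell-by-cell against independently coded lookup-table oracles;
the shipped tests use 9,216 stillbirth, 7,680 neonatal and 3,072
maternal cells.

**Stochastic cohorts** (`cohort_spec()` + `sample_cohort()`) draw each
case's death type and true cause from configurable mixes, emit the sign
pattern the hierarchy maps to that cause (defining sign present,
higher-priority signs absent), then add *noise* — each strictly
lower-priority sign added with probability `noise_rate` — and
*missingness* — each non-defining tri-state field masked to unknown with
probability `missingness_rate`. By construction noise cannot change the
assigned cause (adding a higher-priority sign would change the *true*
cause: that is the hierarchy working as designed, not an error), and
masked fields are inert under the unknown-as-absent convention. Clean
and noisy cohorts therefore admit an exact recovery check, and the
recovered cause fractions estimate the generating mix with multinomial
error. The default death-type mix (45% stillbirth, 45% neonatal, 10%
maternal) and cause mixes (e.g. asphyxia-heavy stillbirths, a roughly
even infection/asphyxia/prematurity split for neonates,
hemorrhage-led maternal deaths) were chosen once as plausible for
low-resource cohorts and are not calibrated to any dataset.

What the generator does **not** emulate: correlated signs (no published
joint distribution exists to copy), sign noise that contradicts the
true cause, measurement error in gestational age or weight, or
fabricated/inconsistent field reports. Passing the recovery tests
therefore demonstrates the engine's internal correctness — precedence,
totality, determinism, missingness handling — and says nothing about
agreement with clinician review or other classification systems on real
deaths, which the source system itself left to future validation.

## Numerical and degenerate-input choices

* Boundary inclusivity: triage uses ≥20 weeks / ≥500 g; all "below
  threshold" rules use strict `<`.
* Neonatal size split with one of GA/BW missing uses the other alone;
  with both missing the infant is treated as term and the trace flags
  the assumption (the alternative — refusing to classify — would break
  totality for exactly the records the system most targets).
* A record with no gestational age, no birth weight and no signs-of-life
  information cannot be triaged and is `not_classifiable` with a
  reason, as are live-born deaths at ≥28 days and maternal deaths
  beyond 6 weeks postpartum.
* Per-row parse failures (e.g. non-numeric gestational age) and
  validation errors yield `not_classifiable` rows with reasons; a batch
  is never aborted by one bad record, and empty cells are missing, not
  errors.
* `classify_batch()` output is a pure function of (records, ruleset):
  re-running is byte-identical, and input order only permutes rows.

## Problem sizes

The shipped test-suite and acceptance script use the grid sizes above
(~20,000 exhaustive cells across the three death types), 10,000-case
cohorts for recovery and calibration checks, and 3-standard-error
multinomial bands for fraction recovery; property-style tests
(monotonicity) sample 60 random records per hierarchy and flip each
absent flag. These sizes were chosen to exercise every rule
combination exhaustively where enumeration is feasible and to keep
Monte-Carlo error far below the effects being checked.

## Known limitations

* Single primary cause only; secondary and contributing causes are out
  of scope by design.
* Cause categories are broad (e.g. no organism-level infection detail);
  ICD-10 compatibility is at the category level, with no code
  cross-mapping.
* The unknown-as-absent convention can demote deaths whose defining
  sign went unrecorded; the unknown-input flags quantify, but do not
  remove, that bias.
* The maternal hierarchy cannot recognize an unreported pregnancy;
  under-ascertainment of maternal deaths is upstream of this system.
* Synthetic cohorts are a verification harness, not an epidemiological
  simulation; observed-vs-generated fraction agreement is a correctness
  check, not a validation against real mortality data.
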