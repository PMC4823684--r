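Package: codassign
Title: Hierarchical Probable Cause-of-Death Assignment for Stillbirths,
    Neonatal Deaths and Maternal Deaths
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic, auditable rules engine that assigns a single
    primary cause of death to stillbirth, neonatal-death and maternal-death
    case records built from minimal, field-collectable data (gestational
    age, birth weight, signs of life, maceration, and tri-state clinical
    sign flags). Cases are first triaged into miscarriage, stillbirth,
    neonatal death or maternal death; each death type is then classified by
    a fixed precedence hierarchy of causes compatible with ICD-10 top-level
    categories. Every assignment carries an ordered rule trace and a
    versioned ruleset so that cohorts can be audited and reclassified when
    thresholds change. Includes CSV/JSON-lines readers with schema
    validation, cohort summaries, a synthetic case generator (exhaustive
    grids and stochastic cohorts with configurable cause mixes, noise and
    missingness), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
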