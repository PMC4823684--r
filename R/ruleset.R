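#' Construct a classification ruleset
#'
#' A ruleset bundles every numeric threshold the triage step and the
#' three cause hierarchies consult, plus a version identifier that is
#' stamped into each assignment. Thresholds are externally
#' configurable (see [read_ruleset()] / [write_ruleset()]) so that a
#' cohort classified today can be reclassified under a revised
#' ruleset later, with the version string documenting which rules
#' produced which assignment.
#'
#' Default values encode the system's published definitions:
#' \describe{
#'   \item{stillbirth_min_weeks / stillbirth_min_grams}{20 weeks (500 g
#'     when gestational age is unavailable): the lower limit separating
#'     stillbirth from miscarriage/abortion.}
#'   \item{maceration_hours_implies_antepartum}{12 h: maceration is read
#'     as fetal death more than this many hours before delivery, hence
#'     antepartum timing.}
#'   \item{neonatal_period_days}{28: live-born deaths at less than this
#'     age are neonatal deaths.}
#'   \item{term_weeks}{37: below this, a neonatal death without anomaly
#'     or infection is never classified unknown.}
#'   \item{neonatal_prematurity_weeks / neonatal_prematurity_grams}{34
#'     weeks / 2000 g: smaller or earlier infants are assigned
#'     complications of prematurity unconditionally (absent anomaly or
#'     infection).}
#'   \item{stillbirth_preterm_weeks / stillbirth_preterm_grams}{32
#'     weeks / 1500 g: the complications-of-preterm-labor rule for
#'     non-macerated stillbirths.}
#'   \item{fever_celsius / hypothermia_celsius}{37.5 / 35.5 C neonatal
#'     temperature criteria (touch-based assessment also satisfies
#'     them).}
#'   \item{bradycardia_bpm / tachycardia_bpm}{120 / 160 beats/min:
#'     fetal heart-rate bounds in the fetal-distress definition
#'     (documented constants; fetal distress itself enters as a
#'     recorded sign).}
#'   \item{hemorrhage_cc}{1000 cc (about 4 cups): blood-loss threshold
#'     for hemorrhage.}
#'   \item{maternal_abortion_weeks}{20: maternal deaths below this
#'     gestation are abortion-related regardless of other signs.}
#'   \item{maternal_postpartum_weeks}{6: maternal deaths are in scope
#'     through this many weeks postpartum.}
#' }
#'
#' @param version identifier string stamped into every assignment.
#' @param ... named threshold overrides (see Details for names).
#' @return An object of class `cod_ruleset` (a named list).
#' @export
#' @examples
#' rs <- default_ruleset()
#' rs$stillbirth_min_weeks
#' ruleset(version = "site-A-2026", stillbirth_preterm_weeks = 30)
ruleset <- function(version = "gn-1.0", ...) {
  rs <- default_ruleset_values()
  over <- list(...)
  bad <- setdiff(names(over), names(rs))
  if (length(bad) > 0L) {
    stop("unknown ruleset field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rs[names(over)] <- over
  rs$version <- as.character(version)
  validate_ruleset(rs)
}

default_ruleset_values <- function() {
  list(
    version = "gn-1.0",
    stillbirth_min_weeks = 20,
    stillbirth_min_grams = 500,
    maceration_hours_implies_antepartum = 12,
    neonatal_period_days = 28,
    term_weeks = 37,
    neonatal_prematurity_weeks = 34,
    neonatal_prematurity_grams = 2000,
    stillbirth_preterm_weeks = 32,
    stillbirth_preterm_grams = 1500,
    fever_celsius = 37.5,
    hypothermia_celsius = 35.5,
    bradycardia_bpm = 120,
    tachycardia_bpm = 160,
    hemorrhage_cc = 1000,
    maternal_abortion_weeks = 20,
    maternal_postpartum_weeks = 6
  )
}

#' @rdname ruleset
#' @export
default_ruleset <- function(version = "gn-1.0") ruleset(version = version)

validate_ruleset <- function(rs) {
  req <- names(default_ruleset_values())
  miss <- setdiff(req, names(rs))
  if (length(miss) > 0L) {
    stop("ruleset missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- setdiff(req, "version")
  for (f in num) {
    v <- rs[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("ruleset field '", f, "' must be a single positive number",
           call. = FALSE)
    }
    rs[[f]] <- as.numeric(v)
  }
  if (!is.character(rs$version) || length(rs$version) != 1L ||
      is.na(rs$version) || !nzchar(rs$version)) {
    stop("ruleset version must be a non-empty string", call. = FALSE)
  }
  if (rs$term_weeks <= rs$neonatal_prematurity_weeks) {
    stop("term_weeks must exceed neonatal_prematurity_weeks", call. = FALSE)
  }
  if (rs$neonatal_prematurity_grams <= rs$stillbirth_preterm_grams) {
    stop("neonatal_prematurity_grams must exceed stillbirth_preterm_grams",
         call. = FALSE)
  }
  rs <- rs[req]
  class(rs) <- "cod_ruleset"
  rs
}

#' Read / write a ruleset configuration file
#'
#' Rulesets serialize to YAML or JSON (chosen by file extension:
#' `.yaml`/`.yml` or `.json`). A round trip reproduces the ruleset
#' exactly; unknown or missing fields are an error, so a config file
#' always describes a complete, valid ruleset.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param rs a `cod_ruleset`.
#' @return `read_ruleset()` returns a validated `cod_ruleset`;
#'   `write_ruleset()` returns `path` invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_ruleset(default_ruleset(), f)
#' identical(read_ruleset(f), default_ruleset())
read_ruleset <- function(path) {
  if (!file.exists(path)) stop("ruleset file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported ruleset format: .", ext, call. = FALSE)
  )
  validate_ruleset(raw)
}

#' @rdname read_ruleset
#' @export
write_ruleset <- function(rs, path) {
  rs <- validate_ruleset(unclass(rs))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(rs)
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported ruleset format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' @export
print.cod_ruleset <- function(x, ...) {
  cat("<cod_ruleset> version:", x$version, "\n")
  num <- setdiff(names(x), "version")
  for (f in num) cat(sprintf("  %-36s %g\n", f, x[[f]]))
  invisible(x)
}
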