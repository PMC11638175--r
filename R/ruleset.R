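#' @title Metadata rulesets
#'
#' @description A ruleset describes, for each of the three FAANG-style
#' documents (`sample`, `experiment`, `analysis`), the fields a record may
#' carry, the requirement tier of each field (`mandatory`, `recommended`,
#' `optional`), the kind of value expected, and — for closed vocabularies —
#' the allowed values. Rulesets are configuration: they are loaded from a
#' versioned JSON file, and the package ships a default single-cell ruleset
#' under `inst/extdata/ruleset_single_cell.json`.
#'
#' @name ruleset
NULL

RULE_TIERS <- c("mandatory", "recommended", "optional")
RULE_KINDS <- c("text", "number", "ontology_term", "date", "file_ref", "entity_ref")
DOC_TYPES <- c("sample", "experiment", "analysis")

#' Construct a single field rule
#'
#' @param name Field name (snake case).
#' @param tier One of `"mandatory"`, `"recommended"`, `"optional"`.
#' @param value_kind One of `"text"`, `"number"`, `"ontology_term"`,
#'   `"date"`, `"file_ref"`, `"entity_ref"`.
#' @param allowed_values Optional character vector closing the vocabulary.
#' @param refers_to For `entity_ref` rules, the document type whose aliases
#'   the value must resolve against (e.g. `"sample"`).
#' @param when Optional named list of field/value pairs; the rule applies to
#'   a record only when all pairs match (used to condition sample-section
#'   rules on the record's `material`).
#' @return A `field_rule` object.
#' @export
field_rule <- function(name, tier, value_kind = "text", allowed_values = NULL,
                       refers_to = NULL, when = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("field rule needs a non-empty name")
  if (!tier %in% RULE_TIERS)
    stop(sprintf("unknown tier \"%s\" for field \"%s\" (expected one of: %s)",
                 tier, name, paste(RULE_TIERS, collapse = ", ")))
  if (!value_kind %in% RULE_KINDS)
    stop(sprintf("unknown value_kind \"%s\" for field \"%s\"", value_kind, name))
  if (identical(value_kind, "entity_ref") && is.null(refers_to))
    stop(sprintf("entity_ref rule \"%s\" needs refers_to", name))
  structure(
    list(name = name, tier = tier, value_kind = value_kind,
         allowed_values = allowed_values, refers_to = refers_to, when = when),
    class = "field_rule"
  )
}

#' Construct a ruleset
#'
#' @param version Non-empty version string.
#' @param sections Named list with entries `sample`, `experiment`,
#'   `analysis`, each an ordered list of [field_rule()]s.
#' @return A `faang_ruleset` object.
#' @export
ruleset <- function(version, sections) {
  if (!is.character(version) || length(version) != 1L || !nzchar(version))
    stop("ruleset version must be a non-empty string")
  missing <- setdiff(DOC_TYPES, names(sections))
  if (length(missing))
    stop(sprintf("missing section: %s", paste(missing, collapse = ", ")))
  for (sec in DOC_TYPES) {
    rules <- sections[[sec]]
    nm <- vapply(rules, function(r) r$name, character(1))
    if (anyDuplicated(nm))
      stop(sprintf("duplicate field rule \"%s\" in section %s",
                   nm[duplicated(nm)][1L], sec))
  }
  structure(list(version = version, sections = sections[DOC_TYPES]),
            class = "faang_ruleset")
}

#' Load a ruleset from a JSON file
#'
#' The file holds an object `{"version": ..., "sections": {"sample": [...],
#' "experiment": [...], "analysis": [...]}}` where each section is an array
#' of field-rule objects (`name`, `tier`, optional `value_kind`,
#' `allowed_values`, `refers_to`, `when`). All three sections must be
#' present and every tier must be one of mandatory/recommended/optional.
#'
#' @param path Path to the ruleset JSON file.
#' @return A `faang_ruleset`.
#' @seealso [default_ruleset()] for the packaged single-cell ruleset.
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) stop(sprintf("ruleset file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$sections)) stop("ruleset file has no \"sections\" object")
  sections <- lapply(raw$sections, function(sec) {
    lapply(sec, function(r) {
      field_rule(
        name = r$name %||% stop("field rule without a name"),
        tier = r$tier %||% stop(sprintf("field \"%s\" has no tier", r$name)),
        value_kind = r$value_kind %||% "text",
        allowed_values = if (!is.null(r$allowed_values))
          vapply(r$allowed_values, as.character, character(1)),
        refers_to = r$refers_to,
        when = r$when
      )
    })
  })
  ruleset(version = raw$version %||% "", sections = sections)
}

#' Write a ruleset to JSON
#'
#' @param rules A `faang_ruleset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(rules, path) {
  stopifnot(inherits(rules, "faang_ruleset"))
  sections <- lapply(rules$sections, function(sec) {
    lapply(sec, function(r) Filter(Negate(is.null), unclass(r)))
  })
  jsonlite::write_json(list(version = rules$version, sections = sections),
                       path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' The packaged default single-cell ruleset
#'
#' Loads the ruleset shipped with the package: a minimal single-cell
#' inventory in which sample records are either organisms (donors) or
#' specimens (distinguished by the mandatory `material` field), experiments
#' describe an scRNA-seq/scATAC-seq library on one specimen, and analysis
#' records describe submitted files.
#'
#' @return A `faang_ruleset`.
#' @export
default_ruleset <- function() {
  load_ruleset(system.file("extdata", "ruleset_single_cell.json",
                           package = "scingest", mustWork = TRUE))
}

#' @export
print.faang_ruleset <- function(x, ...) {
  cat(sprintf("<faang_ruleset v%s>\n", x$version))
  for (sec in names(x$sections)) {
    tiers <- vapply(x$sections[[sec]], function(r) r$tier, character(1))
    cat(sprintf("  %-10s %2d fields (%d mandatory, %d recommended, %d optional)\n",
                sec, length(tiers), sum(tiers == "mandatory"),
                sum(tiers == "recommended"), sum(tiers == "optional")))
  }
  invisible(x)
}

# Rules applicable to one record: every `when` pair must match the record.
applicable_rules <- function(section_rules, record) {
  Filter(function(r) {
    if (is.null(r$when)) return(TRUE)
    all(vapply(names(r$when), function(f) {
      !is.null(record[[f]]) && identical(as.character(record[[f]]),
                                         as.character(r$when[[f]]))
    }, logical(1)))
  }, section_rules)
}
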