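#' @title Submission validation
#' @name validation
NULL

# CURIE syntax for ontology terms, e.g. "NCBITaxon:9823", "UBERON:0000178".
CURIE_PATTERN <- "^[A-Za-z][A-Za-z0-9_]*:[0-9]+$"
DATE_PATTERN <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"

new_issue <- function(record_alias, field, severity, message) {
  data.frame(record_alias = record_alias, field = field,
             severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Construct a validation report
#'
#' Status is `"fail"` exactly when at least one issue has severity
#' `"error"`; warnings alone never fail a report.
#'
#' @param issues Data frame with columns `record_alias`, `field`,
#'   `severity`, `message` (zero rows for a clean pass).
#' @return A `validation_report`.
#' @export
validation_report <- function(issues = NULL) {
  if (is.null(issues) || nrow(issues) == 0L) {
    issues <- data.frame(record_alias = character(0), field = character(0),
                         severity = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  }
  status <- if (any(issues$severity == "error")) "fail" else "pass"
  structure(list(status = status, issues = issues), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  n_err <- sum(x$issues$severity == "error")
  n_warn <- sum(x$issues$severity == "warning")
  cat(sprintf("<validation_report: %s (%d errors, %d warnings)>\n",
              x$status, n_err, n_warn))
  if (nrow(x$issues)) print(utils::head(x$issues, 20L))
  invisible(x)
}

check_value_kind <- function(rule, value, alias) {
  if (rule$value_kind == "ontology_term" && !grepl(CURIE_PATTERN, value)) {
    return(new_issue(alias, rule$name, "error",
                     sprintf("field \"%s\": value \"%s\" is not an ontology CURIE (PREFIX:digits)",
                             rule$name, value)))
  }
  if (rule$value_kind == "date" && !grepl(DATE_PATTERN, value)) {
    return(new_issue(alias, rule$name, "error",
                     sprintf("field \"%s\": value \"%s\" is not an ISO date (YYYY-MM-DD)",
                             rule$name, value)))
  }
  if (rule$value_kind == "number" && is.na(suppressWarnings(as.numeric(value)))) {
    return(new_issue(alias, rule$name, "error",
                     sprintf("field \"%s\": value \"%s\" is not numeric", rule$name, value)))
  }
  NULL
}

#' Validate a submission against a ruleset
#'
#' Per record: a missing mandatory field is an error, a missing recommended
#' field a warning; values outside a rule's `allowed_values` are errors;
#' ontology terms are checked syntactically (CURIE pattern, no live
#' ontology lookup); `entity_ref` values must resolve to an alias in the
#' referenced document (e.g. a specimen's `derived_from` must name an
#' existing organism sample). Problems are reported, never thrown.
#'
#' @param sub A `faang_submission`.
#' @param rules A `faang_ruleset` covering all three document types.
#' @return A `validation_report`; status `"fail"` iff any error.
#' @export
validate_submission <- function(sub, rules) {
  stopifnot(inherits(sub, "faang_submission"), inherits(rules, "faang_ruleset"))
  alias_pool <- lapply(sub[DOC_TYPES], doc_aliases)
  issues <- list()
  add <- function(x) issues[[length(issues) + 1L]] <<- x

  for (d in DOC_TYPES) {
    aliases <- alias_pool[[d]]
    dup <- unique(aliases[duplicated(aliases)])
    for (a in dup)
      add(new_issue(a, "alias", "error",
                    sprintf("duplicate alias \"%s\" in %s document", a, d)))
    for (i in seq_along(sub[[d]]$records)) {
      rec <- sub[[d]]$records[[i]]
      # documents built programmatically may lack an alias; report, don't crash
      alias <- rec$alias %||% sprintf("<%s record %d>", d, i)
      for (rule in applicable_rules(rules$sections[[d]], rec)) {
        value <- rec[[rule$name]]
        if (is.null(value)) {
          if (rule$tier == "mandatory") {
            add(new_issue(alias, rule$name, "error",
                          sprintf("missing mandatory field \"%s\"", rule$name)))
          } else if (rule$tier == "recommended") {
            add(new_issue(alias, rule$name, "warning",
                          sprintf("missing recommended field \"%s\"", rule$name)))
          }
          next
        }
        if (!is.null(rule$allowed_values) && !value %in% rule$allowed_values) {
          add(new_issue(alias, rule$name, "error",
                        sprintf("field \"%s\": value \"%s\" not in allowed set {%s}",
                                rule$name, value,
                                paste(rule$allowed_values, collapse = ", "))))
          next
        }
        if (rule$value_kind == "entity_ref") {
          if (!value %in% alias_pool[[rule$refers_to]]) {
            add(new_issue(alias, rule$name, "error",
                          sprintf("field \"%s\": unresolved reference \"%s\" (no such alias in %s document)",
                                  rule$name, value, rule$refers_to)))
          }
          next
        }
        iss <- check_value_kind(rule, value, alias)
        if (!is.null(iss)) add(iss)
      }
    }
  }
  validation_report(do.call(rbind, issues))
}
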