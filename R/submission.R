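#' @title FAANG-style submissions
#'
#' @description A submission is three flat metadata documents — sample,
#' experiment, analysis — each an ordered list of records keyed by a unique
#' `alias`. Documents can be read from TSV, XLSX or JSON; field names are
#' normalised to lower-case snake case, values are kept verbatim as
#' character strings.
#'
#' @name submission
NULL

# "Sample Name " -> "sample_name"
normalise_field_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Construct a metadata document
#'
#' @param doc_type `"sample"`, `"experiment"` or `"analysis"`.
#' @param records Ordered list of named lists (field -> character value);
#'   each record must carry a non-empty, document-unique `alias`.
#' @param source `"spreadsheet"` or `"json"`.
#' @return A `metadata_document`.
#' @export
metadata_document <- function(doc_type, records, source = "json") {
  if (!doc_type %in% DOC_TYPES)
    stop(sprintf("unknown document type \"%s\"", doc_type))
  records <- lapply(records, function(rec) {
    rec <- rec[vapply(rec, function(v)
      !is.null(v) && !is.na(v) && nzchar(trimws(as.character(v))), logical(1))]
    stats::setNames(lapply(rec, as.character), normalise_field_name(names(rec)))
  })
  aliases <- vapply(records, function(r) r$alias %||% "", character(1))
  if (any(!nzchar(aliases)))
    stop(sprintf("%s document: every record needs a non-empty alias", doc_type))
  if (anyDuplicated(aliases))
    stop(sprintf("duplicate alias \"%s\" in %s document",
                 aliases[duplicated(aliases)][1L], doc_type))
  structure(list(doc_type = doc_type, records = records, source = source),
            class = "metadata_document")
}

doc_aliases <- function(doc) {
  vapply(doc$records, function(r) as.character(r$alias %||% ""), character(1))
}

#' Bundle the three documents into a submission
#'
#' @param sample,experiment,analysis `metadata_document`s of the matching type.
#' @return A `faang_submission`.
#' @export
faang_submission <- function(sample, experiment, analysis) {
  docs <- list(sample = sample, experiment = experiment, analysis = analysis)
  for (d in DOC_TYPES) {
    if (!inherits(docs[[d]], "metadata_document") ||
        !identical(docs[[d]]$doc_type, d))
      stop(sprintf("argument \"%s\" must be a metadata_document of type %s", d, d))
  }
  structure(docs, class = "faang_submission")
}

read_one_document <- function(path, doc_type) {
  if (!file.exists(path))
    stop(sprintf("cannot read %s document: file not found: %s", doc_type, path))
  ext <- tolower(tools::file_ext(path))
  records <- switch(
    ext,
    json = {
      raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
      if (!is.list(raw)) stop(sprintf("%s: expected a JSON array of records", path))
      raw
    },
    tsv = ,
    txt = {
      dt <- data.table::fread(path, sep = "\t", header = TRUE,
                              colClasses = "character", na.strings = "")
      df_to_records(as.data.frame(dt, check.names = FALSE))
    },
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading XLSX needs the readxl package; supply TSV or JSON instead")
      df <- readxl::read_excel(path, sheet = 1L, col_types = "text")
      df_to_records(as.data.frame(df, check.names = FALSE))
    },
    stop(sprintf("unsupported submission format \".%s\" (use tsv, xlsx or json): %s",
                 ext, path))
  )
  metadata_document(doc_type, records,
                    source = if (ext == "json") "json" else "spreadsheet")
}

df_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- lapply(df[i, , drop = FALSE], function(v) as.character(v))
    stats::setNames(row, names(df))
  })
}

#' Read a three-document submission
#'
#' Each path may be TSV (tab-delimited, header row), XLSX (first sheet) or
#' JSON (array of record objects); the three files may mix formats. Field
#' names are normalised to lower-case snake case; values are kept verbatim.
#'
#' @param sample_path,experiment_path,analysis_path File paths.
#' @return A `faang_submission`.
#' @export
read_submission <- function(sample_path, experiment_path, analysis_path) {
  faang_submission(
    sample = read_one_document(sample_path, "sample"),
    experiment = read_one_document(experiment_path, "experiment"),
    analysis = read_one_document(analysis_path, "analysis")
  )
}

#' Write a submission to disk
#'
#' @param sub A `faang_submission`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"json"`.
#' @return Named character vector of the three paths written, invisibly.
#' @export
write_submission <- function(sub, dir, format = c("tsv", "json")) {
  stopifnot(inherits(sub, "faang_submission"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (d in DOC_TYPES) {
    path <- file.path(dir, paste0(d, ".", format))
    if (format == "json") {
      jsonlite::write_json(sub[[d]]$records, path, auto_unbox = TRUE, pretty = TRUE)
    } else {
      fields <- unique(unlist(lapply(sub[[d]]$records, names)))
      rows <- lapply(sub[[d]]$records, function(rec) {
        vals <- vapply(fields, function(f) rec[[f]] %||% NA_character_, character(1))
        as.data.frame(as.list(stats::setNames(vals, fields)),
                      check.names = FALSE, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
      if (is.null(df)) df <- data.frame()
      utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                         row.names = FALSE)
    }
    paths[d] <- path
  }
  invisible(paths)
}

#' @export
print.metadata_document <- function(x, ...) {
  cat(sprintf("<metadata_document %s: %d records (%s)>\n",
              x$doc_type, length(x$records), x$source))
  invisible(x)
}

#' @export
print.faang_submission <- function(x, ...) {
  cat("<faang_submission>\n")
  for (d in DOC_TYPES)
    cat(sprintf("  %-10s %3d records\n", d, length(x[[d]]$records)))
  invisible(x)
}

# Structural equality ignoring the `source` tag: same record order, same
# fields, same values. Used by the round-trip checks.
documents_equal <- function(a, b) {
  if (length(a$records) != length(b$records)) return(FALSE)
  for (i in seq_along(a$records)) {
    ra <- a$records[[i]]; rb <- b$records[[i]]
    if (!setequal(names(ra), names(rb))) return(FALSE)
    if (!all(vapply(names(ra), function(f)
      identical(as.character(ra[[f]]), as.character(rb[[f]])), logical(1))))
      return(FALSE)
  }
  TRUE
}

#' Compare two submissions field-for-field
#'
#' @param a,b `faang_submission`s.
#' @return `TRUE` when all three documents have the same records, in the
#'   same order, with the same fields and values (the `source` tag is
#'   ignored); otherwise `FALSE`.
#' @export
submissions_equal <- function(a, b) {
  all(vapply(DOC_TYPES, function(d) documents_equal(a[[d]], b[[d]]), logical(1)))
}
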