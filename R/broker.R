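#' @title FAANG to HCA brokering
#'
#' @description Converting the three flat FAANG documents into an HCA-style
#' graph requires five adaptations: (1) the recommended tier, absent from
#' the target schema, is dropped; (2) the flat records are split into typed
#' entities; (3) the reference fields become database links; (4) a project
#' entity is synthesised because the source has no project tab; (5) system
#' metadata (`described_by`, schema version, UUID) is injected. [convert()]
#' runs the full pipeline: validate, clean, split, link, graph-validate.
#'
#' @name broker
NULL

#' Construct a project block
#'
#' The source documents carry no project-level information, so it is
#' supplied separately and turned into the graph's single project entity.
#'
#' @param title Non-empty project title.
#' @param description Free-text description.
#' @param contributors List of `list(name=, institution=)`.
#' @param accessions Character vector of study accessions carried verbatim
#'   (e.g. an ENA study accession).
#' @return A `project_block`.
#' @export
project_block <- function(title, description = "", contributors = list(),
                          accessions = character(0)) {
  if (!is.character(title) || length(title) != 1L || !nzchar(title))
    stop("project block needs a non-empty title")
  structure(list(title = title, description = description,
                 contributors = contributors,
                 accessions = as.character(accessions)),
            class = "project_block")
}

#' Conversion options
#'
#' @param drop_recommended Drop recommended-tier fields during cleaning
#'   (default `TRUE`, matching the target schema's mandatory/optional-only
#'   tiers).
#' @param schema_version Version stamped on every entity.
#' @param uuid_namespace Namespace for deterministic UUIDs.
#' @param schema_base Base URI for `described_by`.
#' @param random_uuids Use random instead of name-based UUIDs.
#' @return A `conversion_options` list.
#' @export
conversion_options <- function(drop_recommended = TRUE,
                               schema_version = "1.0.0",
                               uuid_namespace = "scingest",
                               schema_base = DEFAULT_SCHEMA_BASE,
                               random_uuids = FALSE) {
  if (!nzchar(schema_version)) stop("schema_version must be non-empty")
  structure(list(drop_recommended = isTRUE(drop_recommended),
                 schema_version = schema_version,
                 uuid_namespace = uuid_namespace,
                 schema_base = schema_base,
                 random_uuids = isTRUE(random_uuids)),
            class = "conversion_options")
}

#' Drop recommended-tier fields from a validated submission
#'
#' Fields whose ruleset tier is `recommended` are removed (not demoted);
#' mandatory and optional fields — and fields the ruleset does not know —
#' are preserved verbatim. A manifest of removed (document, record, field)
#' triples keeps the operation auditable.
#'
#' @param sub A `faang_submission` that passes [validate_submission()]
#'   (re-validated here; failure is an error).
#' @param rules The `faang_ruleset` defining tiers.
#' @param opts [conversion_options()]; with `drop_recommended = FALSE` the
#'   submission is returned untouched with an empty manifest.
#' @return `list(submission = <cleaned faang_submission>, manifest =
#'   <data.frame doc_type/record_alias/field>)`.
#' @export
clean_documents <- function(sub, rules, opts = conversion_options()) {
  rep <- validate_submission(sub, rules)
  if (rep$status == "fail")
    stop(paste0("submission failed validation; first error: ",
                rep$issues$message[rep$issues$severity == "error"][1L]))
  manifest <- data.frame(doc_type = character(0), record_alias = character(0),
                         field = character(0), stringsAsFactors = FALSE)
  if (!opts$drop_recommended)
    return(list(submission = sub, manifest = manifest))

  for (d in DOC_TYPES) {
    recs <- lapply(sub[[d]]$records, function(rec) {
      rules_rec <- applicable_rules(rules$sections[[d]], rec)
      rec_tiers <- vapply(rules_rec, function(r) r$tier, character(1))
      drop <- intersect(names(rec),
                        vapply(rules_rec, function(r) r$name,
                               character(1))[rec_tiers == "recommended"])
      if (length(drop)) {
        manifest <<- rbind(manifest,
                           data.frame(doc_type = d, record_alias = rec$alias,
                                      field = drop, stringsAsFactors = FALSE))
        rec <- rec[setdiff(names(rec), drop)]
      }
      rec
    })
    sub[[d]] <- metadata_document(d, recs, source = sub[[d]]$source)
  }
  list(submission = sub, manifest = manifest)
}

#' Synthesise the project entity
#'
#' @param meta A [project_block()].
#' @param opts [conversion_options()].
#' @return An `hca_entity` of subcategory `project` whose content carries
#'   title, description, contributors and accessions verbatim.
#' @export
synthesize_project <- function(meta, opts = conversion_options()) {
  stopifnot(inherits(meta, "project_block"))
  e <- entity("project", "project", "project",
              content = list(title = meta$title, description = meta$description),
              schema_version = opts$schema_version, schema_base = opts$schema_base)
  # lists kept structured (not coerced to scalar character)
  e$content$contributors <- lapply(meta$contributors, function(p)
    lapply(p, as.character))
  e$content$accessions <- as.character(meta$accessions)
  e
}

sample_is_specimen <- function(rec) {
  identical(rec$material, "specimen") || !is.null(rec$derived_from)
}

file_subcategory <- function(file_type) {
  if (isTRUE(file_type %in% c("mtx", "h5ad"))) "analysis_file" else "sequence_file"
}

#' Split a cleaned submission into typed entities
#'
#' Mapping: organism sample records become `donor_organism` biomaterials;
#' specimen records become `specimen_from_organism` biomaterials plus a
#' `collection_protocol` and a sampling process entity; each experiment
#' record yields a `library_preparation_protocol` (carrying the full
#' record), a `sequencing_protocol`, and a sequencing process entity; each
#' analysis record becomes a `sequence_file` or `analysis_file` entity; the
#' project block becomes the single project entity. Every entity receives
#' `described_by`, schema version and UUID. Reference fields
#' (`derived_from`, `sample_ref`, `experiment_ref`) stay inside entity
#' content; [build_links()] realises them as links.
#'
#' @param sub Cleaned `faang_submission`.
#' @param project A [project_block()].
#' @param opts [conversion_options()].
#' @return An `entity_graph` with entities but no links yet.
#' @export
split_into_entities <- function(sub, project, opts = conversion_options()) {
  stopifnot(inherits(sub, "faang_submission"))
  ents <- list()
  push <- function(e) {
    e <- assign_uuid(e, opts$uuid_namespace, random = opts$random_uuids)
    ents[[length(ents) + 1L]] <<- e
  }
  mk <- function(id, cat, subcat, content)
    entity(id, cat, subcat, content, schema_version = opts$schema_version,
           schema_base = opts$schema_base)

  push(synthesize_project(project, opts))

  sample_aliases <- doc_aliases(sub$sample)
  exp_aliases <- doc_aliases(sub$experiment)

  # sample records in original order, so flattening restores the document
  for (rec in sub$sample$records) {
    if (sample_is_specimen(rec)) {
      if (!is.null(rec$derived_from) && !rec$derived_from %in% sample_aliases)
        stop(sprintf("specimen \"%s\": unresolved derived_from \"%s\"",
                     rec$alias, rec$derived_from))
      push(mk(rec$alias, "biomaterial", "specimen_from_organism", rec))
      push(mk(paste0(rec$alias, "_collection"), "protocol",
              "collection_protocol", list(alias = rec$alias)))
      push(mk(paste0(rec$alias, "_sampling_process"), "process", "process",
              list(alias = rec$alias)))
    } else {
      push(mk(rec$alias, "biomaterial", "donor_organism", rec))
    }
  }

  for (rec in sub$experiment$records) {
    if (is.null(rec$sample_ref) || !rec$sample_ref %in% sample_aliases)
      stop(sprintf("experiment \"%s\": unresolved sample_ref \"%s\"",
                   rec$alias, rec$sample_ref %||% "<missing>"))
    push(mk(paste0(rec$alias, "_library_preparation"), "protocol",
            "library_preparation_protocol", rec))
    seq_content <- rec[intersect(c("alias", "assay_type", "sequencing_instrument"),
                                 names(rec))]
    push(mk(paste0(rec$alias, "_sequencing"), "protocol",
            "sequencing_protocol", seq_content))
    push(mk(paste0(rec$alias, "_sequencing_process"), "process", "process",
            list(alias = rec$alias)))
  }

  for (rec in sub$analysis$records) {
    if (is.null(rec$experiment_ref) || !rec$experiment_ref %in% exp_aliases)
      stop(sprintf("file \"%s\": unresolved experiment_ref \"%s\"",
                   rec$alias, rec$experiment_ref %||% "<missing>"))
    push(mk(rec$alias, "file", file_subcategory(rec$file_type), rec))
  }

  entity_graph(ents, links = list())
}

#' Realise reference fields as process links
#'
#' Each specimen's `derived_from` becomes a sampling link (input: the named
#' donor; output: the specimen; protocol: its collection protocol). Each
#' experiment becomes one sequencing link from its `sample_ref` specimen to
#' all files whose `experiment_ref` names it (one link per experiment:
#' files of one library share provenance). Reference fields remain in
#' entity content, so the conversion is losslessly flattenable.
#'
#' @param g Graph from [split_into_entities()].
#' @return The graph with links populated.
#' @export
build_links <- function(g) {
  stopifnot(inherits(g, "entity_graph"))
  ids <- names(g$entities)
  links <- list()

  specimens <- entities_of(g, "specimen_from_organism")
  for (sp in specimens) {
    donor <- sp$content$derived_from
    if (is.null(donor) || !donor %in% ids)
      stop(sprintf("cannot link specimen \"%s\": unresolvable reference \"%s\"",
                   sp$entity_id, donor %||% "<missing>"))
    links[[length(links) + 1L]] <- link(
      process_id = paste0(sp$entity_id, "_sampling_process"),
      input_ids = donor, output_ids = sp$entity_id,
      protocol_ids = paste0(sp$entity_id, "_collection"))
  }

  files <- entities_of(g, category = "file")
  file_exp <- vapply(files, function(f) f$content$experiment_ref %||% "",
                     character(1))
  for (lp in entities_of(g, "library_preparation_protocol")) {
    rec <- lp$content
    exp_alias <- rec$alias
    specimen <- rec$sample_ref
    if (is.null(specimen) || !specimen %in% ids)
      stop(sprintf("cannot link experiment \"%s\": unresolvable reference \"%s\"",
                   exp_alias, specimen %||% "<missing>"))
    out_files <- names(files)[file_exp == exp_alias]
    if (length(out_files) == 0L) next  # no files submitted for this library
    links[[length(links) + 1L]] <- link(
      process_id = paste0(exp_alias, "_sequencing_process"),
      input_ids = specimen, output_ids = out_files,
      protocol_ids = c(paste0(exp_alias, "_library_preparation"),
                       paste0(exp_alias, "_sequencing")))
  }

  g$links <- links
  g
}

#' Convert a submission into a validated entity graph
#'
#' Runs the full pipeline in fixed stage order: metadata validation,
#' recommended-field cleaning, entity splitting, link construction, graph
#' validation. Conversion is refused (an error) when metadata validation
#' fails.
#'
#' @param sub A `faang_submission`.
#' @param rules A `faang_ruleset`.
#' @param project A [project_block()].
#' @param opts [conversion_options()].
#' @return `list(graph, metadata_report, graph_report, manifest)` of class
#'   `conversion_result`.
#' @export
convert <- function(sub, rules, project, opts = conversion_options()) {
  metadata_report <- validate_submission(sub, rules)
  if (metadata_report$status == "fail") {
    first <- metadata_report$issues$message[metadata_report$issues$severity == "error"][1L]
    stop(paste0("conversion refused: submission failed validation (", first, ")"))
  }
  cleaned <- clean_documents(sub, rules, opts)
  g <- split_into_entities(cleaned$submission, project, opts)
  g <- build_links(g)
  graph_report <- validate_graph(g)
  structure(list(graph = g, metadata_report = metadata_report,
                 graph_report = graph_report, manifest = cleaned$manifest),
            class = "conversion_result")
}

#' @export
print.conversion_result <- function(x, ...) {
  cat("<conversion_result>\n  metadata: ", x$metadata_report$status,
      "\n  graph:    ", x$graph_report$status, "\n", sep = "")
  print(x$graph)
  invisible(x)
}

#' Export an entity graph as per-type spreadsheets
#'
#' Writes one tab-separated sheet per entity subcategory present in the
#' graph (empty subcategories are omitted), one row per entity, with the
#' system fields (`uuid`, `described_by`, `schema_version`, `entity_id`) in
#' the leading columns followed by the union of content fields.
#'
#' @param g A valid `entity_graph`.
#' @param dir Output directory; one `<subcategory>.tsv` per sheet.
#' @return Named character vector of paths written, invisibly.
#' @export
export_spreadsheet <- function(g, dir) {
  rep <- validate_graph(g)
  if (rep$status == "fail")
    stop("cannot export an invalid graph; run validate_graph() for details")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subcats <- unique(vapply(g$entities, function(e) e$subcategory, character(1)))
  paths <- character(0)
  for (sc in subcats) {
    ents <- entities_of(g, sc)
    fields <- unique(unlist(lapply(ents, function(e)
      names(Filter(is.character, e$content)))))
    rows <- lapply(ents, function(e) {
      sys <- c(uuid = e$uuid, described_by = e$described_by,
               schema_version = e$schema_version, entity_id = e$entity_id)
      vals <- vapply(fields, function(f) {
        v <- e$content[[f]]
        if (is.character(v) && length(v) == 1L) v else NA_character_
      }, character(1))
      as.data.frame(as.list(c(sys, vals)), check.names = FALSE,
                    stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    path <- file.path(dir, paste0(sc, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE)
    paths[sc] <- path
  }
  invisible(paths)
}

#' Re-read a spreadsheet export
#'
#' Inverse of [export_spreadsheet()] at the content level: returns, per
#' subcategory, a data frame with the system columns and content fields as
#' written.
#'
#' @param dir Directory written by [export_spreadsheet()].
#' @return Named list of data frames, one per subcategory sheet.
#' @export
read_spreadsheet_export <- function(dir) {
  files <- c_sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  out <- lapply(files, function(f)
    as.data.frame(data.table::fread(f, sep = "\t", colClasses = "character",
                                    na.strings = ""), check.names = FALSE))
  stats::setNames(out, sub("\\.tsv$", "", basename(files)))
}
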