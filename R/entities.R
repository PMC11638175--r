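#' @title HCA-style entities and links
#'
#' @description The Human Cell Atlas data model describes an assay as a
#' graph of typed entities — one project, biomaterials (donor organisms,
#' specimens, cell suspensions), protocols, processes, and files — where
#' each process link consumes inputs and produces outputs under one or more
#' protocols. Every entity carries system metadata: a `described_by` schema
#' URI, a schema version, and a UUID.
#'
#' @name hca_entities
NULL

# category -> admissible subcategories
SUBCATEGORY_REGISTRY <- list(
  project = "project",
  biomaterial = c("donor_organism", "specimen_from_organism", "cell_suspension"),
  protocol = c("collection_protocol", "dissociation_protocol",
               "library_preparation_protocol", "sequencing_protocol"),
  process = "process",
  file = c("sequence_file", "analysis_file")
)

UUID_PATTERN <- "^[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$"

DEFAULT_SCHEMA_BASE <- "https://schema.scingest.example.org/type"

described_by_uri <- function(subcategory, schema_version,
                             base = DEFAULT_SCHEMA_BASE) {
  paste(base, schema_version, subcategory, sep = "/")
}

#' Construct an entity
#'
#' @param entity_id Unique identifier, typically derived from the source
#'   record's alias.
#' @param category One of project/biomaterial/protocol/process/file.
#' @param subcategory Concrete type from the fixed registry (e.g.
#'   `donor_organism`, `sequencing_protocol`, `sequence_file`).
#' @param content Named list of the entity's biological content.
#' @param schema_version Schema version recorded on the entity.
#' @param schema_base Base URI of the published schema directory; the
#'   `described_by` URI is `<base>/<version>/<subcategory>`.
#' @param uuid Optional pre-assigned UUID; usually left for [assign_uuid()].
#' @return An `hca_entity`.
#' @export
entity <- function(entity_id, category, subcategory, content = list(),
                   schema_version = "1.0.0",
                   schema_base = DEFAULT_SCHEMA_BASE, uuid = NA_character_) {
  if (!is.character(entity_id) || length(entity_id) != 1L || !nzchar(entity_id))
    stop("entity_id must be a non-empty string")
  if (!category %in% names(SUBCATEGORY_REGISTRY))
    stop(sprintf("unknown entity category \"%s\"", category))
  if (!subcategory %in% SUBCATEGORY_REGISTRY[[category]])
    stop(sprintf("subcategory \"%s\" not registered under category \"%s\"",
                 subcategory, category))
  structure(
    list(entity_id = entity_id, category = category, subcategory = subcategory,
         described_by = described_by_uri(subcategory, schema_version, schema_base),
         schema_version = schema_version, uuid = uuid,
         content = lapply(content, as.character)),
    class = "hca_entity"
  )
}

#' Assign a deterministic name-based UUID
#'
#' The UUID is a pure function of `(namespace, category, entity_id)`: the
#' MD5 of that triple laid out in canonical 8-4-4-4-12 form with the
#' version/variant bits of a name-based UUID, so repeated conversions of
#' the same submission are byte-identical and diffable. Set
#' `random = TRUE` for production-like random UUIDs.
#'
#' @param e An `hca_entity`.
#' @param namespace Namespace string scoping the UUIDs of one conversion.
#' @param random Use a random UUID instead of the deterministic scheme.
#' @return The entity with its `uuid` field set.
#' @export
assign_uuid <- function(e, namespace, random = FALSE) {
  stopifnot(inherits(e, "hca_entity"))
  if (!nzchar(e$entity_id)) stop("entity_id must be non-empty")
  hex <- if (random) {
    paste(sprintf("%02x", sample.int(256L, 16L, replace = TRUE) - 1L),
          collapse = "")
  } else {
    digest::digest(paste(namespace, e$category, e$entity_id, sep = ":"),
                   algo = "md5", serialize = FALSE)
  }
  chars <- strsplit(hex, "")[[1]]
  chars[13] <- "3"                                     # version: name-based (MD5)
  chars[17] <- c("8", "9", "a", "b")[1L + strtoi(chars[17], 16L) %% 4L]  # variant
  e$uuid <- paste0(
    paste(chars[1:8], collapse = ""), "-", paste(chars[9:12], collapse = ""), "-",
    paste(chars[13:16], collapse = ""), "-", paste(chars[17:20], collapse = ""),
    "-", paste(chars[21:32], collapse = ""))
  e
}

#' Construct a process link
#'
#' @param process_id Id of the process entity realising the link.
#' @param input_ids,output_ids Ids of consumed / produced biomaterials or
#'   files; both non-empty and disjoint.
#' @param protocol_ids Ids of the protocols the process follows; non-empty.
#' @return An `hca_link`.
#' @export
link <- function(process_id, input_ids, output_ids, protocol_ids) {
  structure(list(process_id = process_id,
                 input_ids = as.character(input_ids),
                 output_ids = as.character(output_ids),
                 protocol_ids = as.character(protocol_ids)),
            class = "hca_link")
}

#' Construct an entity graph
#'
#' @param entities List of `hca_entity` (insertion order is preserved and
#'   meaningful: flattening emits documents in this order).
#' @param links List of `hca_link`.
#' @return An `entity_graph`; use [validate_graph()] to check it.
#' @export
entity_graph <- function(entities = list(), links = list()) {
  ids <- vapply(entities, function(e) e$entity_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate entity_id \"%s\"", ids[duplicated(ids)][1L]))
  names(entities) <- ids
  structure(list(entities = entities, links = links), class = "entity_graph")
}

#' @export
print.entity_graph <- function(x, ...) {
  cats <- vapply(x$entities, function(e) e$category, character(1))
  cat(sprintf("<entity_graph: %d entities, %d links>\n",
              length(x$entities), length(x$links)))
  if (length(cats)) print(table(cats))
  invisible(x)
}

entities_of <- function(g, subcategory = NULL, category = NULL) {
  Filter(function(e) {
    (is.null(subcategory) || e$subcategory %in% subcategory) &&
      (is.null(category) || e$category %in% category)
  }, g$entities)
}

#' Serialise an entity graph to a directory
#'
#' Writes one JSON document per entity (named `<entity_id>.json`, grouped
#' in per-category subdirectories) plus a `links.json` listing each process
#' link's inputs, outputs and protocols.
#'
#' @param g An `entity_graph`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_entity_graph <- function(g, dir) {
  stopifnot(inherits(g, "entity_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in g$entities) {
    sub <- file.path(dir, e$category)
    dir.create(sub, showWarnings = FALSE)
    jsonlite::write_json(
      list(entity_id = e$entity_id, category = e$category,
           subcategory = e$subcategory, described_by = e$described_by,
           schema_version = e$schema_version, uuid = e$uuid,
           content = e$content),
      file.path(sub, paste0(e$entity_id, ".json")),
      auto_unbox = TRUE, pretty = TRUE)
  }
  jsonlite::write_json(
    lapply(g$links, unclass), file.path(dir, "links.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Flatten an entity graph back into a submission
#'
#' Inverse of [convert()]: rebuilds the sample document from donor and
#' specimen biomaterial content, the experiment document from
#' library-preparation protocol content, and the analysis document from
#' file entity content, all in entity insertion order. System fields
#' (uuid, described_by, schema_version) are discarded; link relations are
#' already present as `derived_from` / `sample_ref` / `experiment_ref`
#' fields because conversion retains them in entity content. The function
#' is pure.
#'
#' @param g A valid `entity_graph` (validated internally; invalid graphs
#'   are an error).
#' @return A `faang_submission`.
#' @export
flatten_graph <- function(g) {
  rep <- validate_graph(g)
  if (rep$status == "fail")
    stop(paste0("cannot flatten an invalid graph: ",
                paste(utils::head(rep$issues$message, 3L), collapse = "; ")))
  sample_recs <- lapply(entities_of(g, c("donor_organism", "specimen_from_organism")),
                        function(e) e$content)
  exp_recs <- lapply(entities_of(g, "library_preparation_protocol"),
                     function(e) e$content)
  file_recs <- lapply(entities_of(g, category = "file"), function(e) e$content)
  faang_submission(
    sample = metadata_document("sample", unname(sample_recs)),
    experiment = metadata_document("experiment", unname(exp_recs)),
    analysis = metadata_document("analysis", unname(file_recs))
  )
}
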