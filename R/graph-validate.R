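#' Validate an entity graph
#'
#' Checks the structural invariants of an HCA-style graph and reports
#' problems without throwing:
#' * exactly one project entity;
#' * all link ids (process, inputs, outputs, protocols) resolve to entities;
#' * inputs and outputs of a link are non-empty and disjoint; protocol list
#'   non-empty;
#' * the directed input-to-output graph is acyclic;
#' * no orphan files (every file entity is the output of exactly one link);
#' * every specimen biomaterial is the output of a link whose inputs
#'   include a donor organism;
#' * UUIDs are canonical and collision-free.
#'
#' A graph with no file entities at all passes with a warning.
#'
#' @param g An `entity_graph`.
#' @return A `validation_report` (record_alias column holds entity or
#'   process ids).
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "entity_graph"))
  issues <- list()
  add <- function(id, field, severity, message)
    issues[[length(issues) + 1L]] <<- new_issue(id, field, severity, message)

  ids <- names(g$entities)
  cats <- vapply(g$entities, function(e) e$category, character(1))

  n_proj <- sum(cats == "project")
  if (n_proj == 0L) add("<graph>", "project", "error", "no project entity")
  if (n_proj > 1L)
    add("<graph>", "project", "error",
        sprintf("multiple project entities (%d)", n_proj))

  # uuid form and collisions
  uuids <- vapply(g$entities, function(e) e$uuid, character(1))
  assigned <- !is.na(uuids)
  bad <- assigned & !grepl(UUID_PATTERN, uuids)
  for (id in ids[bad])
    add(id, "uuid", "error", sprintf("malformed uuid \"%s\"", uuids[[id]]))
  dup_uuid <- unique(uuids[assigned][duplicated(uuids[assigned])])
  for (u in dup_uuid)
    add("<graph>", "uuid", "error",
        sprintf("uuid collision: \"%s\" assigned to entities %s", u,
                paste(ids[assigned & uuids == u], collapse = ", ")))
  if (any(!assigned))
    for (id in ids[!assigned]) add(id, "uuid", "error", "entity has no uuid")

  edges <- character(0)  # interleaved from,to pairs over input->output
  file_output_count <- stats::setNames(integer(length(ids)), ids)
  specimen_ok <- stats::setNames(logical(length(ids)), ids)

  for (lk in g$links) {
    pid <- lk$process_id
    for (ref in c(pid, lk$input_ids, lk$output_ids, lk$protocol_ids)) {
      if (!ref %in% ids)
        add(pid, "link", "error", sprintf("dangling link id \"%s\"", ref))
    }
    if (length(lk$input_ids) == 0L)
      add(pid, "link", "error", "process link with empty inputs")
    if (length(lk$output_ids) == 0L)
      add(pid, "link", "error", "process link with empty outputs")
    if (length(lk$protocol_ids) == 0L)
      add(pid, "link", "error", "process link with empty protocols")
    both <- intersect(lk$input_ids, lk$output_ids)
    if (length(both))
      add(pid, "link", "error",
          sprintf("ids appear as both input and output: %s",
                  paste(both, collapse = ", ")))
    for (i in lk$input_ids)
      for (o in lk$output_ids) edges <- c(edges, i, o)

    outs <- intersect(lk$output_ids, ids)
    file_output_count[outs[cats[outs] == "file"]] <-
      file_output_count[outs[cats[outs] == "file"]] + 1L
    donors_in <- any(cats[intersect(lk$input_ids, ids)] == "biomaterial" &
                       vapply(g$entities[intersect(lk$input_ids, ids)],
                              function(e) e$subcategory, character(1)) == "donor_organism")
    if (donors_in) {
      spec_out <- outs[vapply(g$entities[outs], function(e)
        identical(e$subcategory, "specimen_from_organism"), logical(1))]
      specimen_ok[spec_out] <- TRUE
    }
  }

  # cycles over the input->output relation
  if (length(edges)) {
    ig <- igraph::make_graph(edges, directed = TRUE)
    if (!igraph::is_dag(ig))
      add("<graph>", "link", "error",
          "cycle in the input/output relation between entities")
  }

  file_ids <- ids[cats == "file"]
  if (length(file_ids) == 0L) {
    add("<graph>", "file", "warning", "no file entities in graph")
  } else {
    for (id in file_ids[file_output_count[file_ids] == 0L])
      add(id, "file", "error", sprintf("orphan file \"%s\": never a link output", id))
    for (id in file_ids[file_output_count[file_ids] > 1L])
      add(id, "file", "error",
          sprintf("file \"%s\" is an output of %d links (expected exactly 1)",
                  id, file_output_count[[id]]))
  }

  spec_ids <- ids[vapply(g$entities, function(e)
    identical(e$subcategory, "specimen_from_organism"), logical(1))]
  for (id in spec_ids[!specimen_ok[spec_ids]])
    add(id, "biomaterial", "error",
        sprintf("specimen \"%s\" has no donor-rooted path (not the output of a link with a donor input)", id))

  validation_report(do.call(rbind, issues))
}
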