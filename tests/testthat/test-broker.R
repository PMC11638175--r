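test_that("cleaning drops recommended fields with an audit manifest", {
  rules <- default_ruleset()
  cl <- clean_documents(toy_submission(), rules)
  rec <- cl$submission$sample$records[[2]]
  expect_false("health_status" %in% names(rec))
  expect_true("specimen_tissue" %in% names(rec))          # mandatory kept
  expect_true(all(c("breed", "health_status") %in% cl$manifest$field))

  # with nothing recommended present, cleaning is the identity
  bare <- drop_field(toy_submission(), "sample", "pig1", "breed")
  bare <- drop_field(bare, "sample", "pig1_blood", "health_status")
  cl2 <- clean_documents(bare, rules)
  expect_true(submissions_equal(cl2$submission, bare))
  expect_equal(nrow(cl2$manifest), 0)

  # drop_recommended off: identity, empty manifest
  cl3 <- clean_documents(toy_submission(), rules,
                         conversion_options(drop_recommended = FALSE))
  expect_true(submissions_equal(cl3$submission, toy_submission()))
  expect_equal(nrow(cl3$manifest), 0)

  broken <- drop_field(toy_submission(), "experiment", "expA", "assay_type")
  expect_error(clean_documents(broken, rules), "failed validation")
})

test_that("the project entity carries the block verbatim", {
  e <- synthesize_project(project_block(
    title = "Pig PBMC", description = "d", accessions = "PRJEB43826"))
  expect_equal(e$subcategory, "project")
  expect_equal(e$content$title, "Pig PBMC")
  expect_true("PRJEB43826" %in% e$content$accessions)

  minimal <- synthesize_project(project_block(title = "t"))
  expect_equal(length(minimal$content$accessions), 0)
  expect_error(project_block(title = ""), "non-empty title")
})

test_that("the toy conversion yields the hand-counted entity inventory", {
  res <- convert(toy_submission(), default_ruleset(), toy_project())
  g <- res$graph
  cats <- vapply(g$entities, function(e) e$category, character(1))
  expect_equal(sum(cats == "project"), 1)
  expect_equal(sum(cats == "biomaterial"), 2)
  expect_equal(sum(cats == "protocol"), 3)
  expect_equal(sum(cats == "file"), 2)
  expect_equal(length(g$links), 2)
  expect_equal(res$metadata_report$status, "pass")
  expect_equal(res$graph_report$status, "pass")
})

test_that("links realise references: donor -> specimen -> files", {
  g <- toy_graph()
  sampling <- Filter(function(l) "pig1" %in% l$input_ids, g$links)
  expect_length(sampling, 1)
  expect_equal(sampling[[1]]$output_ids, "pig1_blood")

  seq_link <- Filter(function(l) "pig1_blood" %in% l$input_ids, g$links)
  expect_length(seq_link, 1)
  expect_setequal(seq_link[[1]]$output_ids, c("expA_R1", "expA_R2"))
  expect_length(seq_link[[1]]$protocol_ids, 2)

  # donor -> specimen -> file path exists in the induced digraph
  edges <- unlist(lapply(g$links, function(l)
    as.vector(t(expand.grid(l$input_ids, l$output_ids,
                            stringsAsFactors = FALSE)))))
  ig <- igraph::make_graph(edges, directed = TRUE)
  d <- igraph::distances(ig, v = "pig1", to = "expA_R1", mode = "out")
  expect_true(is.finite(d[1, 1]))
})

test_that("unresolvable references are refused with the alias named", {
  sub <- toy_submission()
  sub$experiment$records[[1]]$sample_ref <- "missing_specimen"
  expect_error(convert(sub, default_ruleset(), toy_project()),
               "missing_specimen")
})

test_that("an empty analysis document leaves a file-less graph (warning)", {
  sub <- toy_submission()
  sub$analysis <- metadata_document("analysis", list())
  res <- convert(sub, default_ruleset(), toy_project())
  cats <- vapply(res$graph$entities, function(e) e$category, character(1))
  expect_equal(sum(cats == "file"), 0)
  expect_equal(res$graph_report$status, "pass")
  expect_match(res$graph_report$issues$message, "no file entities", all = FALSE)
})

test_that("conversion is refused when a mandatory field is missing", {
  sub <- drop_field(toy_submission(), "analysis", "expA_R1", "checksum")
  expect_error(convert(sub, default_ruleset(), toy_project()),
               "conversion refused")
})

test_that("flatten(convert(S)) round-trips to clean(S) and is idempotent", {
  rules <- default_ruleset()
  fx <- make_submission(fixture_spec(seed = 11))
  res <- convert(fx$submission, rules, fx$project)
  flat <- flatten_graph(res$graph)
  expect_true(submissions_equal(flat, clean_documents(fx$submission, rules)$submission))

  # converting the flattened documents reproduces the same graph
  res2 <- convert(flat, rules, fx$project)
  expect_setequal(names(res2$graph$entities), names(res$graph$entities))
  expect_equal(length(res2$graph$links), length(res$graph$links))
  uu1 <- vapply(res$graph$entities, function(e) e$uuid, character(1))
  uu2 <- vapply(res2$graph$entities, function(e) e$uuid, character(1))
  expect_identical(uu2[names(uu1)], uu1)
})

test_that("conversion never invents biological content", {
  fx <- make_submission(fixture_spec(seed = 5))
  res <- convert(fx$submission, default_ruleset(), fx$project)
  input_values <- unlist(lapply(unclass(fx$submission), function(doc)
    unlist(lapply(doc$records, unlist))))
  project_values <- unlist(fx$project)
  pool <- c(input_values, project_values)
  for (e in res$graph$entities) {
    vals <- unlist(Filter(is.character, e$content))
    expect_true(all(vals %in% pool),
                info = sprintf("entity %s has invented content", e$entity_id))
  }
})

test_that("spreadsheet export has system columns and re-reads verbatim", {
  g <- toy_graph()
  dir <- tempfile()
  export_spreadsheet(g, dir)
  sheets <- read_spreadsheet_export(dir)
  expect_true(all(c("project", "donor_organism", "specimen_from_organism",
                    "library_preparation_protocol", "sequencing_protocol",
                    "collection_protocol", "process", "sequence_file") %in%
                    names(sheets)))
  # no analysis_file entities in the toy graph -> sheet omitted
  expect_false("analysis_file" %in% names(sheets))

  donors <- sheets$donor_organism
  expect_equal(names(donors)[1:4],
               c("uuid", "described_by", "schema_version", "entity_id"))
  e <- g$entities[["pig1"]]
  expect_equal(donors$uuid, e$uuid)
  for (f in c("alias", "material", "organism", "sex"))
    expect_equal(donors[[f]], e$content[[f]])
})
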