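test_that("cell-type selection restricts cells and keeps genes", {
  ex <- make_expression(fixture_spec())
  sel <- select_cells(ex$matrix, ex$metadata, "CD4_T")
  expect_equal(nrow(sel), nrow(ex$matrix))
  expect_equal(ncol(sel), sum(ex$metadata$celltype == "CD4_T"))
  expect_equal(ncol(sel), 50)  # 200 cells round-robin over 4 labels

  expect_error(select_cells(ex$matrix, ex$metadata, "T_reg"),
               "available: B, CD4_T, Mono, NK")
  # label known to the metadata but covering no matrix cell
  meta2 <- rbind(ex$metadata, data.frame(cell_id = "ghost", celltype = "DC"))
  expect_error(select_cells(ex$matrix, meta2, "DC"), "covers no cell")
  expect_identical(select_cells(ex$matrix, ex$metadata, NULL), ex$matrix)
})

test_that("a planted driver TF outranks an independent noise TF", {
  withr::with_seed(99, {
    n <- 200
    m <- rbind(TF1 = rnorm(n), TF2 = rnorm(n))
    m <- rbind(m, y = 2 * m["TF1", ] + rnorm(n, sd = 0.1))
    colnames(m) <- sprintf("c%03d", 1:n)
  })
  edges <- infer_network(m, c("TF1", "TF2"), grn_config(seed = 7))
  to_y <- edges[edges$target == "y", ]
  expect_gt(to_y$importance[to_y$tf == "TF1"],
            to_y$importance[to_y$tf == "TF2"])
  expect_equal(to_y$importance[to_y$tf == "TF1"],
               max(edges$importance))  # strongest edge overall
})

test_that("zero-variance targets get exactly zero importance; no self-edges", {
  withr::with_seed(1, {
    m <- rbind(TF1 = rnorm(50), TF2 = rnorm(50), flat = rep(3, 50),
               g1 = rnorm(50))
    colnames(m) <- sprintf("c%02d", 1:50)
  })
  edges <- infer_network(m, c("TF1", "TF2"), grn_config(n_trees = 10, seed = 1))
  expect_identical(edges$importance[edges$target == "flat"], c(0, 0))
  expect_false(any(edges$tf == edges$target))
  # TF genes appear as targets of the other TF only
  expect_equal(sum(edges$target == "TF1"), 1)

  # constant predictors: zero importances, not an error
  const <- m; const["TF1", ] <- 1; const["TF2", ] <- 2
  e2 <- infer_network(const, c("TF1", "TF2"), grn_config(n_trees = 5, seed = 1))
  expect_true(all(e2$importance[e2$target == "g1"] == 0))
})

test_that("inference is deterministic and invariant to cell permutation", {
  ex <- make_expression(fixture_spec(n_genes = 12, n_targets = 5, n_cells = 60))
  cfg <- grn_config(n_trees = 20, seed = 42)
  tfs <- rownames(ex$adjacency)
  e1 <- infer_network(ex$matrix, tfs, cfg)
  e2 <- infer_network(ex$matrix, tfs, cfg)
  expect_identical(e1, e2)

  perm <- withr::with_seed(5, sample(ncol(ex$matrix)))
  e3 <- infer_network(ex$matrix[, perm], tfs, cfg)
  expect_identical(e3, e1)
  expect_true(all(e1$importance >= 0))
})

test_that("TF matching is case-insensitive and failures are informative", {
  ex <- make_expression(fixture_spec(n_genes = 10, n_targets = 3, n_cells = 40))
  cfg <- grn_config(n_trees = 5, seed = 1)
  e_lower <- suppressWarnings(
    infer_network(ex$matrix, c("tf1", "tf2", "NOPE"), cfg))
  expect_setequal(unique(e_lower$tf), c("TF1", "TF2"))
  expect_warning(infer_network(ex$matrix, c("TF1", "TF2", "NOPE"), cfg),
                 "not in the matrix")
  expect_error(infer_network(ex$matrix, "TF1", cfg), "fewer than 2 TFs")
  expect_error(infer_network(ex$matrix[, 1:3], c("TF1", "TF2"), cfg),
               "at least 5 cells")
})

test_that("edge ranking sorts, breaks ties lexicographically and truncates", {
  t <- structure(data.frame(
    tf = c("a", "b", "b", "a"), target = c("x", "x", "y", "y"),
    importance = c(0.5, 0.9, 0.5, 0.5)),
    class = c("edge_table", "data.frame"))
  r <- rank_edges(t)
  expect_equal(r$rank, 1:4)
  expect_equal(r$tf[1], "b"); expect_equal(r$target[1], "x")
  # the three tied 0.5 edges come in (tf, target) lexicographic order
  expect_equal(paste(r$tf[2:4], r$target[2:4]), c("a x", "a y", "b y"))

  top <- rank_edges(t, top_n = 2)
  expect_equal(nrow(top), 2)
  expect_equal(top$rank, 1:2)
})

test_that("hub scores sum outgoing importances", {
  star <- structure(data.frame(
    tf = c(rep("A", 5), "B"), target = c(paste0("t", 1:5), "t1"),
    importance = c(rep(1, 5), 2)), class = c("edge_table", "data.frame"))
  h <- hub_scores(star)
  expect_equal(h[["A"]], 5)
  expect_equal(names(h)[1], "A")
  expect_length(hub_scores(star[6, , drop = FALSE]), 1)
  expect_length(hub_scores(star[0, , drop = FALSE]), 0)
})

test_that("importance ordering agrees with an independent forest on a planted pair", {
  skip_if_not_installed("randomForest")
  withr::with_seed(123, {
    n <- 200
    X <- cbind(TF1 = rnorm(n), TF2 = rnorm(n), TF3 = rnorm(n))
    y <- 2 * X[, "TF1"] + 0.8 * X[, "TF2"] + rnorm(n, sd = 0.2)
  })
  rf <- withr::with_seed(123,
    randomForest::randomForest(X, y, ntree = 200, importance = FALSE))
  ref <- rf$importance[, "IncNodePurity"]
  m <- rbind(t(X), y = y)
  colnames(m) <- sprintf("c%03d", 1:n)
  ours <- infer_network(m, c("TF1", "TF2", "TF3"),
                        grn_config(n_trees = 200, seed = 3))
  ours_y <- ours[ours$target == "y", ]
  expect_equal(ours_y$tf[order(-ours_y$importance)],
               names(ref)[order(-ref)])
})

test_that("the HTML export is self-contained and embeds the edge list", {
  t <- structure(data.frame(
    tf = c("TF1", "TF1", "TF2"), target = c("g1", "g2", "g1"),
    importance = c(3, 2, 1), rank = 1:3), class = c("edge_table", "data.frame"))
  path <- tempfile(fileext = ".html")
  export_html(t, path)
  html <- paste(readLines(path), collapse = "\n")
  expect_false(grepl("https?://", sub(".*<body>", "", html)))  # no fetches
  payload <- sub(".*<script type=\"application/json\" id=\"network-data\">", "", html)
  payload <- sub("</script>.*", "", payload)
  parsed <- jsonlite::fromJSON(payload, simplifyVector = FALSE)
  expect_length(parsed$edges, 3)
  expect_lte(length(parsed$nodes), 6)
  got <- vapply(parsed$edges, function(e)
    paste(e$tf, e$target, e$importance), character(1))
  expect_setequal(got, paste(t$tf, t$target, t$importance))
  roles <- vapply(parsed$nodes, function(n) n$role, character(1))
  expect_setequal(unique(roles), c("tf", "target"))

  empty <- t[0, ]
  path2 <- tempfile(fileext = ".html")
  export_html(empty, path2)
  expect_match(paste(readLines(path2), collapse = "\n"), "no edges")
})
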