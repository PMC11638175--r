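# Shared in-code fixtures for the suite. Everything is generated at test
# time; nothing is read from disk except files the tests themselves write.

toy_submission <- function() {
  # 1 organism, 1 specimen, 1 experiment, 2 fastq files
  faang_submission(
    sample = metadata_document("sample", list(
      list(alias = "pig1", material = "organism", organism = "NCBITaxon:9823",
           sex = "female", breed = "Duroc"),
      list(alias = "pig1_blood", material = "specimen",
           specimen_tissue = "UBERON:0000178", derived_from = "pig1",
           health_status = "healthy")
    )),
    experiment = metadata_document("experiment", list(
      list(alias = "expA", assay_type = "scRNA-seq",
           library_construction = "10x 3' v3", sample_ref = "pig1_blood")
    )),
    analysis = metadata_document("analysis", list(
      list(alias = "expA_R1", file_name = "expA_R1.fastq", file_type = "fastq",
           checksum = "aa11", experiment_ref = "expA"),
      list(alias = "expA_R2", file_name = "expA_R2.fastq", file_type = "fastq",
           checksum = "bb22", experiment_ref = "expA")
    ))
  )
}

toy_project <- function() {
  project_block(title = "toy", accessions = "PRJEB43826")
}

toy_graph <- function() {
  convert(toy_submission(), default_ruleset(), toy_project())$graph
}

# delete one field from one record of one document; bypasses the document
# constructor so that even alias deletion yields a checkable submission
drop_field <- function(sub, doc, alias, field) {
  recs <- lapply(sub[[doc]]$records, function(r) {
    if (identical(r$alias, alias)) r[setdiff(names(r), field)] else r
  })
  sub[[doc]]$records <- recs
  sub
}

# brute-force per-type pseudobulk used as the collapse oracle
collapse_oracle <- function(m, meta, stat = "mean") {
  labels <- setNames(meta$celltype, meta$cell_id)
  types <- sort(unique(unname(labels[colnames(m)])), method = "radix")
  out <- matrix(NA_real_, nrow(m), length(types),
                dimnames = list(rownames(m), types))
  for (g in rownames(m)) {
    for (ct in types) {
      vals <- c()
      for (cell in colnames(m)) {
        if (labels[[cell]] == ct) vals <- c(vals, m[g, cell])
      }
      out[g, ct] <- if (stat == "mean") mean(vals) else median(vals)
    }
  }
  out
}

# exhaustive depth-1 regression split search: returns the best midpoint
# threshold and its decrease in residual sum of squares
exhaustive_split_oracle <- function(x, y) {
  n <- length(y)
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  total <- sse(y)
  best <- list(threshold = NA_real_, reduction = 0)
  xs <- sort(unique(x))
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    left <- y[x <= thr]; right <- y[x > thr]
    red <- total - sse(left) - sse(right)
    if (red > best$reduction + 1e-12) best <- list(threshold = thr, reduction = red)
  }
  best
}

# label TF->target candidate edges against a planted adjacency
planted_labels <- function(edges, adjacency) {
  keep <- !(edges$target %in% rownames(adjacency))
  edges <- edges[keep, , drop = FALSE]
  lab <- mapply(function(tf, tg) {
    if (tg %in% colnames(adjacency)) adjacency[tf, tg] else 0L
  }, edges$tf, edges$target)
  list(edges = edges, labels = as.integer(lab))
}
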