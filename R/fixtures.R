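#' @title Synthetic fixtures
#'
#' @description Generators for every input the toolkit consumes, so the
#' whole pipeline runs offline: a PBMC-like seven-donor submission (one
#' specimen per donor, one scRNA-seq experiment per specimen, two FASTQ
#' records per experiment, plus a project block), a planted linear-network
#' expression matrix with cell-type labels and its ground-truth adjacency,
#' and a toy two-chromosome gene annotation. All generators are pure
#' functions of the spec (seed included).
#'
#' @name fixtures
NULL

#' Fixture specification
#'
#' Defaults mirror the emulated study design at toy scale: seven donors
#' (the source study's seven pigs), 200 cells, 40 genes of which 5 are
#' transcription factors, 15 planted targets with 2 TF parents each
#' (effect sizes Uniform(1, 3)), observation noise sd 0.1; the remaining
#' 20 non-TF genes are independent noise genes.
#'
#' @param n_donors Number of donor organisms (default 7).
#' @param n_cells Number of cells (default 200).
#' @param n_genes Total genes (default 40).
#' @param n_tfs Transcription factors among them (default 5).
#' @param n_targets Planted targets (default 15).
#' @param parents_per_target TF parents per planted target (default 2).
#' @param noise_sd Target observation noise sd (default 0.1).
#' @param seed RNG seed (default 1).
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_donors = 7L, n_cells = 200L, n_genes = 40L,
                         n_tfs = 5L, n_targets = 15L,
                         parents_per_target = 2L, noise_sd = 0.1, seed = 1L) {
  spec <- list(n_donors = as.integer(n_donors), n_cells = as.integer(n_cells),
               n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
               n_targets = as.integer(n_targets),
               parents_per_target = as.integer(parents_per_target),
               noise_sd = noise_sd, seed = as.integer(seed))
  counts <- unlist(spec[c("n_donors", "n_cells", "n_genes", "n_tfs",
                          "n_targets", "parents_per_target")])
  if (any(counts < 1L)) stop("all fixture counts must be positive")
  if (spec$n_tfs >= spec$n_genes) stop("n_tfs must be smaller than n_genes")
  if (spec$n_tfs + spec$n_targets > spec$n_genes)
    stop("n_tfs + n_targets must not exceed n_genes")
  if (spec$parents_per_target > spec$n_tfs)
    stop("parents_per_target cannot exceed n_tfs")
  structure(spec, class = "fixture_spec")
}

FIXTURE_CELLTYPES <- c("CD4_T", "B", "NK", "Mono")
FIXTURE_ACCESSION <- "PRJEB43826"

#' Generate a PBMC-like submission
#'
#' Sample document: `n_donors` organism records (pig-like: NCBITaxon term,
#' sex, breed) followed by one blood specimen per donor (`derived_from`
#' set); one scRNA-seq experiment per specimen; two FASTQ analysis records
#' per experiment; a project block citing the emulated study accession.
#' Byte-identical under the same seed.
#'
#' @param spec A [fixture_spec()].
#' @return `list(submission = faang_submission, project = project_block)`.
#' @export
make_submission <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_private_seed(spec$seed, {
    breeds <- c("Duroc", "Landrace", "Yorkshire", "Berkshire", "Hampshire")
    organisms <- lapply(seq_len(spec$n_donors), function(i) {
      list(alias = sprintf("pig%d", i), material = "organism",
           organism = "NCBITaxon:9823",
           sex = sample(c("male", "female"), 1L),
           breed = sample(breeds, 1L))
    })
    specimens <- lapply(seq_len(spec$n_donors), function(i) {
      rec <- list(alias = sprintf("pig%d_blood", i), material = "specimen",
                  specimen_tissue = "UBERON:0000178",
                  derived_from = sprintf("pig%d", i))
      if (runif(1) < 0.5) rec$health_status <- "healthy"
      rec
    })
    experiments <- lapply(seq_len(spec$n_donors), function(i) {
      list(alias = sprintf("exp%d", i), assay_type = "scRNA-seq",
           library_construction = "10x 3' v3",
           sample_ref = sprintf("pig%d_blood", i),
           sequencing_instrument = "Illumina NovaSeq 6000")
    })
    analyses <- unlist(lapply(seq_len(spec$n_donors), function(i) {
      lapply(1:2, function(r) {
        list(alias = sprintf("exp%d_R%d", i, r),
             file_name = sprintf("exp%d_S1_L001_R%d_001.fastq", i, r),
             file_type = "fastq",
             checksum = paste(sprintf("%02x", sample(0:255, 16L, replace = TRUE)),
                              collapse = ""),
             experiment_ref = sprintf("exp%d", i))
      })
    }), recursive = FALSE)
    sub <- faang_submission(
      sample = metadata_document("sample", c(organisms, specimens)),
      experiment = metadata_document("experiment", experiments),
      analysis = metadata_document("analysis", analyses)
    )
    project <- project_block(
      title = "Synthetic porcine PBMC single-cell ingestion fixture",
      description = paste("Synthetic stand-in emulating a seven-donor pig",
                          "PBMC scRNA-seq submission at toy scale."),
      contributors = list(list(name = "Fixture Generator",
                               institution = "scingest")),
      accessions = FIXTURE_ACCESSION
    )
    list(submission = sub, project = project)
  })
}

#' Generate a planted-network expression matrix
#'
#' TF expressions are i.i.d. Normal(0, 1) across cells. Each of the
#' `n_targets` planted targets is a linear combination of its
#' `parents_per_target` randomly chosen TF parents with effect sizes drawn
#' Uniform(1, 3), plus Normal(0, `noise_sd`) noise; remaining non-TF genes
#' are independent Normal(0, 1) noise genes. The whole matrix is shifted
#' by its global minimum so values are non-negative (count-score
#' compatible). Cells are labelled round-robin over CD4_T, B, NK, Mono.
#'
#' @param spec A [fixture_spec()].
#' @return `list(matrix, metadata, adjacency, effects)`: the genes x cells
#'   matrix, the `cell_id`/`celltype` data frame, the planted TF x target
#'   0/1 adjacency matrix, and the matching effect-size matrix.
#' @export
make_expression <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_private_seed(spec$seed, {
    tf_ids <- sprintf("TF%d", seq_len(spec$n_tfs))
    other_ids <- sprintf("G%d", seq_len(spec$n_genes - spec$n_tfs))
    target_ids <- other_ids[seq_len(spec$n_targets)]
    cell_ids <- sprintf("cell%03d", seq_len(spec$n_cells))

    tf_expr <- matrix(rnorm(spec$n_tfs * spec$n_cells), nrow = spec$n_tfs,
                      dimnames = list(tf_ids, cell_ids))
    adjacency <- matrix(0L, nrow = spec$n_tfs, ncol = spec$n_targets,
                        dimnames = list(tf_ids, target_ids))
    effects <- matrix(0, nrow = spec$n_tfs, ncol = spec$n_targets,
                      dimnames = list(tf_ids, target_ids))

    m <- matrix(0, nrow = spec$n_genes, ncol = spec$n_cells,
                dimnames = list(c(tf_ids, other_ids), cell_ids))
    m[tf_ids, ] <- tf_expr
    for (tg in target_ids) {
      parents <- sample(tf_ids, spec$parents_per_target)
      eff <- runif(spec$parents_per_target, 1, 3)
      adjacency[parents, tg] <- 1L
      effects[parents, tg] <- eff
      m[tg, ] <- drop(eff %*% tf_expr[parents, , drop = FALSE]) +
        rnorm(spec$n_cells, sd = spec$noise_sd)
    }
    noise_ids <- setdiff(other_ids, target_ids)
    if (length(noise_ids))
      m[noise_ids, ] <- matrix(rnorm(length(noise_ids) * spec$n_cells),
                               nrow = length(noise_ids))
    m <- m - min(m)

    metadata <- data.frame(
      cell_id = cell_ids,
      celltype = rep_len(FIXTURE_CELLTYPES, spec$n_cells),
      stringsAsFactors = FALSE
    )
    list(matrix = m, metadata = metadata, adjacency = adjacency,
         effects = effects)
  })
}

#' Generate a toy gene annotation
#'
#' One record per gene of [make_expression()], split evenly over two
#' chromosomes, non-overlapping 1 kb intervals on a 2 kb grid, alternating
#' strands, `gene_name = gene_id + "_sym"`. Deterministic (placement is a
#' pure function of the spec).
#'
#' @param spec A [fixture_spec()].
#' @return Annotation data frame (`chrom`, `start`, `end`, `gene_id`,
#'   `gene_name`, `strand`).
#' @export
make_annotation <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_genes
  tf_ids <- sprintf("TF%d", seq_len(spec$n_tfs))
  other_ids <- sprintf("G%d", seq_len(n - spec$n_tfs))
  ids <- c(tf_ids, other_ids)
  half <- ceiling(n / 2)
  chrom <- rep(c("chr1", "chr2"), times = c(half, n - half))
  pos_in_chrom <- c(seq_len(half), seq_len(n - half)) - 1L
  start <- pos_in_chrom * 2000L
  data.frame(
    chrom = chrom, start = start, end = start + 1000L,
    gene_id = ids, gene_name = paste0(ids, "_sym"),
    strand = rep_len(c("+", "-"), n),
    stringsAsFactors = FALSE
  )
}

#' Write an annotation as BED6 or GFF3
#'
#' @param ann Annotation data frame.
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    lines <- paste(ann$chrom, ann$start, ann$end, ann$gene_id, 0L, ann$strand,
                   sep = "\t")
    writeLines(lines, path)
  } else {
    attrs <- sprintf("ID=%s;gene_id=%s;Name=%s", ann$gene_id, ann$gene_id,
                     ann$gene_name)
    lines <- paste(ann$chrom, "scingest", "gene", ann$start + 1L, ann$end,
                   ".", ann$strand, ".", attrs, sep = "\t")
    writeLines(c("##gff-version 3", lines), path)
  }
  invisible(path)
}

#' Write the full fixture set to a directory
#'
#' Emits every file the command-line tools consume: `sample.tsv`,
#' `experiment.tsv`, `analysis.tsv`, `project.json`, `ruleset.json` (the
#' packaged default), `exprMatrix.tsv`, `meta.tsv`, `genes.bed`,
#' `genes.gff3`, `tfs.txt`, and the planted truth `adjacency.tsv`.
#'
#' @param dir Output directory.
#' @param spec A [fixture_spec()].
#' @return Invisibly, the named vector of paths written.
#' @export
write_fixtures <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sub <- make_submission(spec)
  expr <- make_expression(spec)
  ann <- make_annotation(spec)

  paths <- write_submission(sub$submission, dir, format = "tsv")
  pj <- file.path(dir, "project.json")
  jsonlite::write_json(unclass(sub$project), pj, auto_unbox = TRUE, pretty = TRUE)
  rs <- file.path(dir, "ruleset.json")
  file.copy(system.file("extdata", "ruleset_single_cell.json",
                        package = "scingest", mustWork = TRUE), rs,
            overwrite = TRUE)
  mx <- file.path(dir, "exprMatrix.tsv")
  write_expression_matrix(expr$matrix, mx)
  mt <- file.path(dir, "meta.tsv")
  data.table::fwrite(expr$metadata, mt, sep = "\t", quote = FALSE)
  bed <- write_annotation(ann, file.path(dir, "genes.bed"), "bed")
  gff <- write_annotation(ann, file.path(dir, "genes.gff3"), "gff3")
  tf <- file.path(dir, "tfs.txt")
  writeLines(c("# fixture transcription factors", rownames(expr$adjacency)), tf)
  adj <- file.path(dir, "adjacency.tsv")
  utils::write.table(expr$adjacency, adj, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(c(paths, project = pj, ruleset = rs, matrix = mx, meta = mt,
              bed = bed, gff3 = gff, tfs = tf, adjacency = adj))
}
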