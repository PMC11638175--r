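#' @title barChart BED track generation
#'
#' @description A genes-by-cells expression matrix is collapsed into a
#' genes-by-cell-types matrix (pseudobulk by mean or median), joined to a
#' gene annotation, and written as a sorted barChart BED track — one BED6
#' row per gene plus the gene symbol, the number of cell types, and the
#' per-cell-type expression vector — the data a genome browser's barChart
#' renderer consumes. Coordinates are BED convention throughout: 0-based,
#' half-open; GFF3 input is shifted on read.
#'
#' @name track_builder
NULL

#' Read a genes-by-cells expression matrix from TSV
#'
#' First column gene id, remaining columns one per cell.
#'
#' @param path TSV path.
#' @return Numeric matrix, rownames gene ids, colnames cell ids.
#' @export
read_expression_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  genes <- as.character(dt[[1L]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene id \"%s\" in matrix", genes[duplicated(genes)][1L]))
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- genes
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell ids in matrix")
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix (genes x cells).
#' @param path Output TSV.
#' @param id_col Header of the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read per-cell metadata
#'
#' @param path TSV with first column cell id and a cell-type column.
#' @param celltype_col Name of the cell-type column (default `"celltype"`).
#' @return Data frame with columns `cell_id`, `celltype`.
#' @export
read_cell_metadata <- function(path, celltype_col = "celltype") {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = "character"))
  if (!celltype_col %in% names(dt))
    stop(sprintf("metadata has no column \"%s\" (columns: %s)", celltype_col,
                 paste(names(dt), collapse = ", ")))
  out <- data.frame(cell_id = as.character(dt[[1L]]),
                    celltype = dt[[celltype_col]], stringsAsFactors = FALSE)
  if (any(!nzchar(out$celltype) | is.na(out$celltype)))
    stop("empty cell-type labels in metadata")
  out
}

#' Read a gene annotation (BED6 or GFF3)
#'
#' BED input is taken as-is (0-based half-open, `name` used as both gene id
#' and gene name). GFF3 input keeps `gene`-type features only, shifts start
#' by -1, and takes the gene id from `gene_id`/`ID` and the name from
#' `Name`/`gene_name` attributes.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return Data frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `gene_name`, `strand`.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      gene_id = as.character(gr$name),
      gene_name = as.character(gr$name),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    g <- rtracklayer::readGFF(path)
    g <- g[g$type == "gene", , drop = FALSE]
    gene_id <- if (!is.null(g$gene_id)) as.character(g$gene_id) else as.character(g$ID)
    gene_name <- if (!is.null(g$Name)) as.character(g$Name)
      else if (!is.null(g$gene_name)) as.character(g$gene_name) else gene_id
    gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
    data.frame(
      chrom = as.character(g$seqid), start = as.integer(g$start) - 1L,
      end = as.integer(g$end), gene_id = gene_id, gene_name = gene_name,
      strand = ifelse(is.na(as.character(g$strand)), ".", as.character(g$strand)),
      stringsAsFactors = FALSE
    )
  }
}

#' Collapse an expression matrix by cell type
#'
#' Pseudobulk aggregation: entry (gene, type) is the `stat` (mean or
#' median) of the gene's expression over cells carrying that label.
#' Columns are ordered by lexicographic (C-locale) cell-type label — the
#' fixed global ordering every downstream record uses.
#'
#' @param m Numeric matrix, genes x cells (colnames are cell ids).
#' @param meta Data frame with `cell_id`, `celltype` covering every matrix
#'   cell (a matrix cell missing from the metadata is an error).
#' @param stat `"mean"` (default) or `"median"`.
#' @return Numeric matrix, genes x cell types.
#' @export
collapse_by_celltype <- function(m, meta, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  labels <- stats::setNames(meta$celltype, meta$cell_id)
  missing <- setdiff(colnames(m), meta$cell_id)
  if (length(missing))
    stop(sprintf("cells absent from metadata: %s%s",
                 paste(utils::head(missing, 5L), collapse = ", "),
                 if (length(missing) > 5L) ", ..." else ""))
  cell_types <- c_sort(unique(unname(labels[colnames(m)])))
  if (length(cell_types) == 0L) stop("no cell types to collapse over")
  out <- vapply(cell_types, function(ct) {
    cols <- colnames(m)[labels[colnames(m)] == ct]
    sub <- m[, cols, drop = FALSE]
    if (stat == "mean") rowMeans(sub) else apply(sub, 1L, stats::median)
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), cell_types))
  out
}

#' Build barChart BED records
#'
#' One record per annotated gene present in the collapsed matrix, in
#' annotation order; genes without annotation are skipped with a message
#' giving the count. `exp_scores` holds the per-cell-type expression in
#' the collapsed matrix's fixed column order; the BED score is the gene's
#' maximum expression scaled to 0-1000 against the global maximum (0 when
#' the global maximum is 0).
#'
#' @param collapsed Genes x cell-types matrix from [collapse_by_celltype()].
#' @param ann Annotation data frame from [read_annotation()] or
#'   [make_annotation()].
#' @return A `barchart_bed` data frame: `chrom`, `start`, `end`, `name`
#'   (gene id), `score`, `strand`, `name2` (gene name), `exp_count`, and a
#'   list-column `exp_scores`; attribute `celltypes` records the column
#'   ordering.
#' @export
make_barchart_bed <- function(collapsed, ann) {
  keep <- ann$gene_id %in% rownames(collapsed)
  if (!any(keep))
    stop("no overlap between matrix genes and annotation gene ids")
  n_skipped <- sum(!rownames(collapsed) %in% ann$gene_id)
  if (n_skipped > 0L)
    message(sprintf("%d matrix gene(s) without annotation skipped", n_skipped))
  ann <- ann[keep, , drop = FALSE]
  scores <- collapsed[ann$gene_id, , drop = FALSE]
  gene_max <- apply(scores, 1L, max)
  global_max <- max(gene_max)
  bed_score <- if (global_max > 0) as.integer(round(1000 * gene_max / global_max))
    else rep(0L, nrow(ann))
  rec <- data.frame(
    chrom = ann$chrom, start = as.integer(ann$start), end = as.integer(ann$end),
    name = ann$gene_id, score = bed_score, strand = ann$strand,
    name2 = ann$gene_name, exp_count = ncol(scores),
    stringsAsFactors = FALSE
  )
  rec$exp_scores <- lapply(seq_len(nrow(scores)), function(i) unname(scores[i, ]))
  rownames(rec) <- NULL
  structure(rec, celltypes = colnames(collapsed),
            class = c("barchart_bed", "data.frame"))
}

#' Sort barChart records in bedSort order
#'
#' Lexicographic (C-locale) chromosome, then ascending start, then
#' ascending end; stable for full ties. Note lexicographic order places
#' `chr10` before `chr2`, matching the browser tool chain.
#'
#' @param records A `barchart_bed` data frame.
#' @return The records reordered.
#' @export
sort_records <- function(records) {
  ord <- c_order(records$chrom, records$start, records$end)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, celltypes = attr(records, "celltypes"),
            class = class(records))
}

records_sorted <- function(records) {
  identical(c_order(records$chrom, records$start, records$end),
            seq_len(nrow(records)))
}

# exact decimal text for doubles (round-trips through as.numeric)
fmt_num <- function(x) {
  vapply(x, function(v) {
    s <- sprintf("%.17g", v)
    short <- sprintf("%.15g", v)
    if (as.numeric(short) == v) short else s
  }, character(1))
}

#' Write a barChart BED track
#'
#' Tab-separated, BED6 columns first (`chrom`, `start`, `end`, `name`,
#' `score`, `strand`), then per dialect: `plus3` adds `name2`, `expCount`
#' and the comma-joined `expScores`; `plus4` (default) adds a literal `"0"`
#' offset placeholder; `plus5` adds a second `"0"` length placeholder. The
#' placeholders are non-functional and exist only to match column counts
#' of browser barChart conventions. Records must already be sorted.
#'
#' @param records Sorted `barchart_bed` records.
#' @param path Output file.
#' @param dialect `"plus4"` (default, 10 columns), `"plus3"` (9) or
#'   `"plus5"` (11).
#' @return `path`, invisibly.
#' @export
write_barchart_bed <- function(records, path, dialect = c("plus4", "plus3", "plus5")) {
  dialect <- match.arg(dialect)
  if (!records_sorted(records))
    stop("records are not sorted; run sort_records() first")
  scores_txt <- vapply(records$exp_scores,
                       function(s) paste(fmt_num(s), collapse = ","), character(1))
  cols <- list(records$chrom, records$start, records$end, records$name,
               records$score, records$strand, records$name2,
               records$exp_count, scores_txt)
  if (dialect %in% c("plus4", "plus5")) cols <- c(cols, list(rep("0", nrow(records))))
  if (dialect == "plus5") cols <- c(cols, list(rep("0", nrow(records))))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a barChart BED track back into records
#'
#' @param path File written by [write_barchart_bed()].
#' @param dialect Dialect it was written with.
#' @return A `barchart_bed` data frame.
#' @export
read_barchart_bed <- function(path, dialect = c("plus4", "plus3", "plus5")) {
  dialect <- match.arg(dialect)
  n_fields <- switch(dialect, plus3 = 9L, plus4 = 10L, plus5 = 11L)
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad))
    stop(sprintf("line %d has %d fields, expected %d for dialect %s",
                 bad[1L], lengths(parts)[bad[1L]], n_fields, dialect))
  rec <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    name = vapply(parts, `[[`, "", 4L),
    score = as.integer(vapply(parts, `[[`, "", 5L)),
    strand = vapply(parts, `[[`, "", 6L),
    name2 = vapply(parts, `[[`, "", 7L),
    exp_count = as.integer(vapply(parts, `[[`, "", 8L)),
    stringsAsFactors = FALSE
  )
  rec$exp_scores <- lapply(parts, function(p)
    as.numeric(strsplit(p[[9L]], ",", fixed = TRUE)[[1L]]))
  structure(rec, class = c("barchart_bed", "data.frame"))
}
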