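#' @title Regulatory-network inference
#'
#' @description For every gene in the expression matrix, an ensemble of
#' regression trees predicts that gene's expression from the expression of
#' the transcription factors (excluding the gene itself when it is a TF).
#' The importance of the edge TF -> gene is the TF's variance-reduction
#' (impurity-decrease) importance averaged over the trees; all edges are
#' pooled, ranked by importance, and the total outgoing importance of a TF
#' is its hub score. Results are deterministic given the configuration
#' seed and invariant to cell order (cells are canonically ordered by id
#' before fitting).
#'
#' @name grn_inference
NULL

#' Read a transcription-factor list
#'
#' Plain text, one symbol per line; `#` starts a comment; blanks ignored.
#'
#' @param path File path.
#' @return Character vector of unique symbols.
#' @export
read_tf_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  syms <- unique(lines[nzchar(lines)])
  if (length(syms) == 0L) stop("TF list is empty")
  syms
}

#' Network-inference configuration
#'
#' @param n_trees Trees per target-gene ensemble (default 100).
#' @param max_features Features tried per split: `"sqrt"` (default), a
#'   fraction in (0, 1], or `"all"`.
#' @param seed Integer seed; the whole inference is a pure function of it.
#' @param cell_type_filter Optional label; when set, [infer_network()]
#'   restricts the matrix with [select_cells()] first.
#' @param min_node_size Minimum samples per leaf (default 5).
#' @param max_depth Maximum tree depth, 0 = unlimited (default).
#' @param bootstrap Bootstrap-resample cells per tree (default `TRUE`).
#' @param method `"rf"` (exhaustive splits, default) or `"extratrees"`
#'   (random thresholds).
#' @param normalize Divide each target's importances by their sum
#'   (default `FALSE`: raw, per-target sums may differ).
#' @return A `grn_config`.
#' @export
grn_config <- function(n_trees = 100L, max_features = "sqrt", seed = 1L,
                       cell_type_filter = NULL, min_node_size = 5L,
                       max_depth = 0L, bootstrap = TRUE,
                       method = c("rf", "extratrees"), normalize = FALSE) {
  method <- match.arg(method)
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("n_trees must be >= 1")
  structure(list(n_trees = n_trees, max_features = max_features,
                 seed = as.integer(seed), cell_type_filter = cell_type_filter,
                 min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth),
                 bootstrap = isTRUE(bootstrap), method = method,
                 normalize = isTRUE(normalize)),
            class = "grn_config")
}

#' Restrict a matrix to cells of one type
#'
#' @param m Genes x cells matrix.
#' @param meta Data frame `cell_id`, `celltype`.
#' @param label Cell-type label to keep.
#' @return The matrix restricted to cells with that label (gene set
#'   unchanged). Unknown labels, or labels covering no matrix cell, are
#'   errors listing the available labels.
#' @export
select_cells <- function(m, meta, label) {
  if (is.null(label)) return(m)
  available <- c_sort(unique(meta$celltype))
  if (!label %in% available)
    stop(sprintf("unknown cell type \"%s\" (available: %s)", label,
                 paste(available, collapse = ", ")))
  keep <- meta$cell_id[meta$celltype == label]
  keep <- intersect(colnames(m), keep)
  if (length(keep) == 0L)
    stop(sprintf("cell type \"%s\" covers no cell of the matrix (available: %s)",
                 label, paste(available, collapse = ", ")))
  m[, keep, drop = FALSE]
}

resolve_mtry <- function(max_features, p) {
  if (identical(max_features, "sqrt")) return(max(1L, floor(sqrt(p))))
  if (identical(max_features, "all")) return(p)
  frac <- suppressWarnings(as.numeric(max_features))
  if (is.na(frac) || frac <= 0 || frac > 1)
    stop("max_features must be \"sqrt\", \"all\", or a fraction in (0, 1]")
  max(1L, floor(frac * p))
}

#' Infer a TF -> target network
#'
#' Per target gene, fits `cfg$n_trees` regression trees (bootstrap +
#' random feature subsets by default) predicting the gene from the TF
#' expressions and averages each TF's total variance reduction across
#' trees. A zero-variance target yields exactly zero importances (there is
#' no impurity to reduce); TF self-edges are excluded by construction. TF
#' symbols are matched to matrix gene ids case-insensitively; unmatched
#' symbols are reported with a warning, not fatal.
#'
#' @param m Genes x cells matrix.
#' @param tfs Character vector of TF symbols.
#' @param cfg [grn_config()].
#' @param meta Optional cell metadata, required when
#'   `cfg$cell_type_filter` is set.
#' @return An `edge_table` data frame (`tf`, `target`, `importance`,
#'   `rank`) sorted by importance, all TF x target pairs included.
#' @export
infer_network <- function(m, tfs, cfg = grn_config(), meta = NULL) {
  stopifnot(is.matrix(m))
  if (!is.null(cfg$cell_type_filter)) {
    if (is.null(meta)) stop("cell_type_filter set but no metadata supplied")
    m <- select_cells(m, meta, cfg$cell_type_filter)
  }
  if (ncol(m) < 5L) stop("need at least 5 cells to fit the ensembles")

  idx <- match(tolower(tfs), tolower(rownames(m)))
  unmatched <- tfs[is.na(idx)]
  if (length(unmatched))
    warning(sprintf("%d TF symbol(s) not in the matrix: %s",
                    length(unmatched),
                    paste(utils::head(unmatched, 5L), collapse = ", ")))
  tf_genes <- rownames(m)[idx[!is.na(idx)]]
  if (length(tf_genes) < 2L)
    stop("fewer than 2 TFs present in the expression matrix")

  # canonical cell order: results must not depend on column permutation
  m <- m[, c_order(colnames(m)), drop = FALSE]
  targets <- rownames(m)
  tf_expr <- t(m[tf_genes, , drop = FALSE])

  edges <- vector("list", length(targets))
  for (k in seq_along(targets)) {
    g <- targets[k]
    preds <- setdiff(tf_genes, g)
    if (length(preds) == 0L) next
    y <- m[g, ]
    if (stats::var(y) == 0) {
      imp <- rep(0, length(preds))
    } else {
      X <- tf_expr[, preds, drop = FALSE]
      fit <- .tree_ensemble_importance(
        X, y, n_trees = cfg$n_trees,
        mtry = resolve_mtry(cfg$max_features, ncol(X)),
        min_node = cfg$min_node_size, max_depth = cfg$max_depth,
        bootstrap = cfg$bootstrap,
        extra_trees = identical(cfg$method, "extratrees"),
        seed = (cfg$seed + k) %% .Machine$integer.max)
      imp <- fit$importance
      if (cfg$normalize && sum(imp) > 0) imp <- imp / sum(imp)
    }
    edges[[k]] <- data.frame(tf = preds, target = g, importance = imp,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, edges)
  rownames(tab) <- NULL
  rank_edges(structure(tab, class = c("edge_table", "data.frame")))
}

#' Rank edges by importance
#'
#' Sorts descending by importance, breaking ties by (tf, target)
#' lexicographic order, reassigns ranks 1..N, and optionally truncates.
#'
#' @param t An `edge_table` (or data frame with `tf`, `target`,
#'   `importance`).
#' @param top_n Optional row cap.
#' @return The re-ranked `edge_table`.
#' @export
rank_edges <- function(t, top_n = NULL) {
  ord <- c_order(-t$importance, t$tf, t$target)
  out <- t[ord, c("tf", "target", "importance"), drop = FALSE]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("edge_table", "data.frame"))
}

#' Hub scores
#'
#' A TF's hub score is the sum of the importances of its outgoing edges;
#' the regulator with the largest score is the network's strongest hub.
#'
#' @param t An `edge_table`.
#' @return Named numeric vector, sorted descending (empty for an empty
#'   table).
#' @export
hub_scores <- function(t) {
  if (nrow(t) == 0L) return(stats::setNames(numeric(0), character(0)))
  s <- vapply(split(t$importance, t$tf), sum, numeric(1))
  s[c_order(-s, names(s))]
}

#' Write an edge table to TSV
#'
#' @param t An `edge_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(t, path) {
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge table from TSV
#'
#' @param path TSV with columns `tf`, `target`, `importance`, `rank`.
#' @return An `edge_table`.
#' @export
read_edge_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df, class = c("edge_table", "data.frame"))
}
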