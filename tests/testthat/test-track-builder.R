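test_that("collapse matches hand-computed means and handles edge shapes", {
  m <- matrix(c(1, 2, 3, 4,
                0, 0, 0, 0,
                2, 4, 6, 8), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:4)))
  meta <- data.frame(cell_id = paste0("c", 1:4),
                     celltype = c("A", "A", "B", "B"))
  got <- collapse_by_celltype(m, meta, "mean")
  expect_equal(got["g1", "A"], mean(c(1, 2)))
  expect_equal(got["g1", "B"], mean(c(3, 4)))
  expect_equal(unname(got["g2", ]), c(0, 0))        # all-zero gene stays zero
  expect_equal(colnames(got), c("A", "B"))          # lexicographic order

  # all cells one type: collapsed column equals row means
  meta1 <- data.frame(cell_id = paste0("c", 1:4), celltype = "only")
  one <- collapse_by_celltype(m, meta1, "mean")
  expect_equal(unname(one[, "only"]), unname(rowMeans(m)))

  # median statistic
  med <- collapse_by_celltype(m, meta, "median")
  expect_equal(med["g1", "A"], median(c(1, 2)))

  expect_error(collapse_by_celltype(m, meta[-1, ], "mean"),
               "absent from metadata")
})

test_that("collapse equals the brute-force oracle on random matrices", {
  withr::with_seed(42, {
    for (i in 1:5) {
      ng <- sample(3:20, 1); nc <- sample(6:40, 1)
      m <- matrix(rexp(ng * nc), ng, nc,
                  dimnames = list(sprintf("g%d", 1:ng), sprintf("c%d", 1:nc)))
      meta <- data.frame(cell_id = colnames(m),
                         celltype = sample(c("x", "y", "z"), nc, replace = TRUE))
      for (stat in c("mean", "median")) {
        expect_equal(collapse_by_celltype(m, meta, stat),
                     collapse_oracle(m, meta, stat), tolerance = 1e-12)
      }
    }
  })
})

test_that("barChart records score on the global max and keep strand", {
  coll <- matrix(c(1.5, 0, 2,
                   3, 1, 0.5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("TF1", "G1"), c("A", "B", "C")))
  ann <- data.frame(chrom = c("chr1", "chr1"), start = c(0L, 2000L),
                    end = c(1000L, 3000L), gene_id = c("TF1", "G1"),
                    gene_name = c("TF1_sym", "G1_sym"), strand = c("+", "-"))
  rec <- make_barchart_bed(coll, ann)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$exp_count, c(3L, 3L))
  expect_equal(rec$exp_scores[[1]], c(1.5, 0, 2))
  # G1 holds the global max -> score exactly 1000; TF1 scaled against it
  expect_equal(rec$score[rec$name == "G1"], 1000L)
  expect_equal(rec$score[rec$name == "TF1"], as.integer(round(1000 * 2 / 3)))
  expect_equal(rec$strand[rec$name == "G1"], "-")

  # all-zero matrix -> all scores zero, not NaN
  zero <- make_barchart_bed(coll * 0, ann)
  expect_equal(zero$score, c(0L, 0L))

  # genes without annotation are skipped with a message, missing overlap errors
  expect_message(make_barchart_bed(rbind(coll, extra = c(1, 1, 1)), ann),
                 "without annotation")
  expect_error(make_barchart_bed(coll, transform(ann, gene_id = c("x", "y"))),
               "no overlap")
})

test_that("sorting follows bedSort order (lexicographic chrom, then coords)", {
  rec <- make_barchart_bed(
    matrix(1:3, 3, 1, dimnames = list(c("a", "b", "c"), "T")),
    data.frame(chrom = c("chr2", "chr10", "chr2"), start = c(5L, 1L, 2L),
               end = c(9L, 4L, 9L), gene_id = c("a", "b", "c"),
               gene_name = c("a", "b", "c"), strand = "+"))
  sorted <- sort_records(rec)
  expect_equal(sorted$chrom, c("chr10", "chr2", "chr2"))  # chr10 before chr2
  expect_equal(sorted$start, c(1L, 2L, 5L))
  expect_identical(sort_records(sorted), sorted)          # already sorted: unchanged

  # same chrom + start: tie broken by end
  tie <- rec
  tie$chrom <- "chr1"; tie$start <- 0L; tie$end <- c(30L, 10L, 20L)
  expect_equal(sort_records(tie)$end, c(10L, 20L, 30L))
})

test_that("track dialects emit 9/10/11 fields and round-trip", {
  ex <- make_expression(fixture_spec(seed = 2))
  coll <- collapse_by_celltype(ex$matrix, ex$metadata)
  rec <- sort_records(make_barchart_bed(coll, make_annotation(fixture_spec(seed = 2))))
  for (spec in list(c("plus3", 9L), c("plus4", 10L), c("plus5", 11L))) {
    path <- tempfile(fileext = ".bed")
    write_barchart_bed(rec, path, spec[[1]])
    fields <- lengths(strsplit(readLines(path), "\t", fixed = TRUE))
    expect_true(all(fields == as.integer(spec[[2]])))
    back <- read_barchart_bed(path, spec[[1]])
    expect_equal(back$exp_scores, rec$exp_scores)
    expect_equal(back[names(back) != "exp_scores"],
                 as.data.frame(rec)[names(back)[names(back) != "exp_scores"]],
                 ignore_attr = TRUE)
  }
  # scores serialised without trailing comma
  line1 <- strsplit(readLines(write_barchart_bed(rec, tempfile(), "plus3"))[1],
                    "\t")[[1]]
  expect_false(grepl(",$", line1[9]))

  expect_error(write_barchart_bed(rec[rev(seq_len(nrow(rec))), ], tempfile()),
               "not sorted")
})

test_that("conservation: mean x member count recovers gene totals", {
  ex <- make_expression(fixture_spec(seed = 4))
  coll <- collapse_by_celltype(ex$matrix, ex$metadata)
  counts <- table(ex$metadata$celltype)[colnames(coll)]
  recovered <- coll %*% as.numeric(counts)
  expect_equal(unname(drop(recovered)), unname(rowSums(ex$matrix)),
               tolerance = 1e-9)
})

test_that("BED and GFF3 annotation readers agree (GFF3 shifted to 0-based)", {
  ann <- make_annotation(fixture_spec(seed = 1))
  bed <- tempfile(fileext = ".bed"); gff <- tempfile(fileext = ".gff3")
  write_annotation(ann, bed, "bed")
  write_annotation(ann, gff, "gff3")
  from_bed <- read_annotation(bed)
  from_gff <- read_annotation(gff)
  expect_equal(from_bed[c("chrom", "start", "end", "gene_id", "strand")],
               ann[c("chrom", "start", "end", "gene_id", "strand")],
               ignore_attr = TRUE)
  expect_equal(from_gff[c("chrom", "start", "end", "gene_id", "strand")],
               ann[c("chrom", "start", "end", "gene_id", "strand")],
               ignore_attr = TRUE)
  expect_equal(from_gff$gene_name, ann$gene_name)  # names survive via GFF3 only
})
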