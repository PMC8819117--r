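test_that("uniform depth normalizes to all-ones coverage", {
  dir <- withr::local_tempdir()
  gm <- make_gene_model(single_exon_bed, dir)
  # 5 identical full-length reads -> depth 5 at every percentile position
  recs <- data.frame(chrom = "chr1", pos = rep(1000L, 5L), cigar = "100M")
  bam <- write_toy_bam(recs, dir)
  cv <- compute_cell_coverage(bam, gm, cell_id = "c1")
  expect_equal(cv$raw_counts, rep(5L, 100L))
  expect_equal(cv$values, rep(1, 100L))
  expect_equal(cv$total_assigned, 5L)
  expect_false(cv$zero_flag)
})

test_that("a cell with no alignments yields the documented all-zero vector", {
  dir <- withr::local_tempdir()
  gm <- make_gene_model(single_exon_bed, dir)
  bam <- write_toy_bam(
    data.frame(chrom = character(0), pos = integer(0), cigar = character(0)),
    dir, stem = "empty")
  cv <- compute_cell_coverage(bam, gm, cell_id = "empty")
  expect_equal(cv$values, rep(0, 100L))
  expect_equal(cv$total_assigned, 0L)
  expect_true(cv$zero_flag)
  expect_false(anyNA(cv$values))
})

test_that("3'-restricted reads cover only the last percentiles", {
  dir <- withr::local_tempdir()
  gm <- make_gene_model(
    "chr1\t1000\t1200\ttx200\t0\t+\t1000\t1200\t0\t1\t200,\t0,", dir)
  # every read covers exactly the last 20 nt (positions 1180-1199)
  recs <- data.frame(chrom = "chr1", pos = rep(1180L, 7L), cigar = "20M")
  bam <- write_toy_bam(recs, dir, stem = "tail")
  cv <- compute_cell_coverage(bam, gm, cell_id = "tail")
  oracle <- pileup_oracle(recs, gm)
  expect_equal(cv$raw_counts, oracle)
  expect_equal(cv$values[1:90], rep(0, 90L))
  expect_equal(cv$values[91:100], rep(1, 10L))
})

test_that("N and D CIGAR gaps do not cover the reference", {
  dir <- withr::local_tempdir()
  gm <- make_gene_model(single_exon_bed, dir)
  # 10M at the start, 80 skipped, 10M at the end; plus a read with a deletion
  recs <- data.frame(chrom = "chr1", pos = c(1000L, 1000L),
                     cigar = c("10M80N10M", "10M5D10M"))
  bam <- write_toy_bam(recs, dir, stem = "gaps")
  cv <- compute_cell_coverage(bam, gm, cell_id = "gaps")
  expect_equal(cv$raw_counts, pileup_oracle(recs, gm))
  expect_equal(cv$raw_counts[1:10], rep(2L, 10L))   # both leading M blocks
  expect_equal(cv$raw_counts[11:15], rep(0L, 5L))   # D gap uncovered
  expect_equal(cv$raw_counts[16:25], rep(1L, 10L))  # second M of the del read
  expect_equal(cv$raw_counts[30:80], rep(0L, 51L))  # N gap uncovered
})

test_that("toy BAM coverage equals the pileup oracle on both strands", {
  dir <- withr::local_tempdir()
  tb <- generate_toy_bam(dir, n_cells = 3L, reads_per_cell = 40L, seed = 42L)
  gm <- load_gene_model(tb$bed)
  for (id in tb$cell_ids) {
    cv <- compute_cell_coverage(tb$bam[[id]], gm, cell_id = id)
    expect_identical(cv$raw_counts, tb$truth[[id]])
    expect_true(all(cv$values >= 0 & cv$values <= 1))
    expect_equal(max(cv$values), 1)
  }
  # the 3'-skewed cell peaks in the high percentiles
  skew_cv <- compute_cell_coverage(tb$bam[[3L]], gm)
  expect_gt(which.max(skew_cv$raw_counts), 60L)
})

test_that("barcode splitting routes records exactly and counts discards", {
  dir <- withr::local_tempdir()
  recs <- data.frame(chrom = "chr1", pos = rep(1000L, 10L), cigar = "100M",
                     tag = rep("AAAC-1", 10L))
  bam <- write_toy_bam(recs, dir, stem = "bc")
  man <- barcode_manifest("AAAC", suffix_policy = "strip")
  sp <- split_by_barcode(bam, man)
  expect_equal(sp$routed, 10L)
  expect_equal(sp$discarded, 0L)
  expect_length(sp$streams[["AAAC"]], 10L)

  # untagged records are discarded and counted
  recs2 <- rbind(recs, data.frame(chrom = "chr1", pos = 1000L,
                                  cigar = "100M", tag = NA))
  bam2 <- write_toy_bam(recs2, dir, stem = "bc2")
  sp2 <- split_by_barcode(bam2, man)
  expect_equal(sp2$routed, 10L)
  expect_equal(sp2$discarded, 1L)

  # nothing routed is a hard error
  expect_error(split_by_barcode(bam, barcode_manifest("TTTT")), "tag_name")
})

test_that("interleaved barcodes split like a naive per-barcode scan", {
  dir <- withr::local_tempdir()
  tags <- rep(c("AAAA", "CCCC", "GGGG"), times = 4L)  # interleaved
  recs <- data.frame(chrom = "chr1",
                     pos = 1000L + seq_along(tags),
                     cigar = "20M", tag = tags)
  bam <- write_toy_bam(recs, dir, stem = "ilv")
  sp <- split_by_barcode(bam, barcode_manifest(c("AAAA", "CCCC", "GGGG")))
  full <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(tag = "CB"))
  for (bc in c("AAAA", "CCCC", "GGGG")) {
    naive <- full[S4Vectors::mcols(full)$CB == bc]  # one pass per barcode
    got <- sp$streams[[bc]]
    expect_length(got, 4L)
    expect_equal(IRanges::start(got), IRanges::start(naive))
  }
})

test_that("split-then-cover equals direct per-cell coverage", {
  dir <- withr::local_tempdir()
  tb <- generate_toy_bam(dir, n_cells = 3L, reads_per_cell = 25L,
                         barcoded = TRUE, seed = 9L)
  gm <- load_gene_model(tb$bed)
  sp <- split_by_barcode(tb$bam, barcode_manifest(tb$barcodes))
  cm <- coverage_matrix(sp, gm)
  for (id in tb$cell_ids) {
    expect_identical(
      as.integer(round(cm$values[id, ] * max(tb$truth[[id]]))),
      tb$truth[[id]])
  }
  expect_equal(sp$discarded, 2L)  # the untagged records
})

test_that("coverage matrix keeps row order and is worker-count invariant", {
  dir <- withr::local_tempdir()
  tb <- generate_toy_bam(dir, n_cells = 4L, reads_per_cell = 15L, seed = 5L)
  gm <- load_gene_model(tb$bed)
  cm1 <- coverage_matrix(tb$bam, gm, workers = 1L)
  cm2 <- coverage_matrix(tb$bam, gm, workers = 4L)
  expect_equal(cm1$cell_ids, tb$cell_ids)
  expect_identical(cm1$values, cm2$values)
  expect_equal(dim(cm1$values), c(4L, 100L))

  dup <- tb$bam[c(1L, 1L)]
  expect_error(coverage_matrix(dup, gm), "duplicate cell ids")
})

test_that("normalization is idempotent", {
  raw <- c(0L, 3L, 9L, rep(1L, 97L))
  v1 <- covskew:::new_coverage_vector("x", raw, 10L)
  v2 <- covskew:::new_coverage_vector("x", as.integer(v1$values * 9L), 10L)
  expect_equal(v1$values, v2$values)
  expect_equal(max(v1$values), 1)
})
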