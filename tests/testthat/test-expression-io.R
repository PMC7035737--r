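test_that("count matrix round-trips through TSV", {
  x <- tiny_sim(n_genes = 10, tissues = "0-L")
  counts <- x$sim$counts[, 1:6]
  samples <- x$sim$samples[1:6, ]
  tmp <- withr::local_tempdir()
  cp <- file.path(tmp, "c.tsv"); sp <- file.path(tmp, "s.tsv")
  write_counts(counts, samples, cp, sp)
  back <- read_counts(cp, sp)
  expect_equal(unname(back$counts), unname(counts))
  expect_identical(dimnames(back$counts), dimnames(counts))
  expect_identical(back$samples$sample_id, samples$sample_id)
})

test_that("sheet/matrix mismatches and malformed counts are located", {
  x <- tiny_sim(n_genes = 5, tissues = "0-L")
  counts <- x$sim$counts[, 1:6]
  samples <- x$sim$samples[1:6, ]
  tmp <- withr::local_tempdir()
  cp <- file.path(tmp, "c.tsv"); sp <- file.path(tmp, "s.tsv")
  write_counts(counts, samples, cp, sp)
  # drop one sample from the sheet: error must name it
  write_tsv_hash(samples[-3, ], sp)
  expect_error(read_counts(cp, sp), samples$sample_id[3], fixed = TRUE)
  # fractional count: error names gene and sample
  write_tsv_hash(samples, sp)
  lines <- readLines(cp)
  lines[3] <- sub("\t(\\d+)", "\t3.7", lines[3])
  writeLines(lines, cp)
  expect_error(read_counts(cp, sp), "format error.*G00002")
})

test_that("FPKM follows the definition and its invariances", {
  counts <- matrix(c(100L, 900L), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  catalog <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                        start = c(1, 5000), end = c(1000, 6999),
                        strand = "+", length = c(1000, 2000))
  # library size 1e6 total is enforced via a filler gene
  counts2 <- rbind(counts, filler = 999000L)
  catalog2 <- rbind(catalog, data.frame(gene_id = "filler", chrom = "chr1",
                                        start = 10000, end = 10999,
                                        strand = "+", length = 1000))
  f <- compute_fpkm(counts2, catalog2)
  expect_equal(f["g1", "s1"], 100)      # 100 frags / 1 kb / 1 M frags
  # scale invariance: doubling every count in the sample leaves FPKM fixed
  f2 <- compute_fpkm(counts2 * 2L, catalog2)
  expect_equal(f2, f)
  # zero count => zero FPKM; monotone in count at fixed library
  expect_equal(compute_fpkm(rbind(counts2[1, , drop = FALSE] * 0L,
                                  counts2[-1, , drop = FALSE] +
                                    c(100L, 0L)),
                            catalog2)["g1", "s1"], 0)
  expect_error(compute_fpkm(counts2 * 0L, catalog2), "zero library")
  expect_error(compute_fpkm(counts2, catalog2[-1, ]), "annotation error")
})

test_that("replicate QC flags low and undefined correlations", {
  x <- tiny_sim(n_genes = 200, tissues = "0-L")
  fpkm <- compute_fpkm(x$sim$counts, x$catalog)
  qc <- replicate_qc(fpkm, x$sim$samples)
  expect_true(all(qc$pairs$r > 0.8))
  expect_equal(sum(qc$pairs$flagged), 0)
  # duplicated replicate columns give r exactly 1
  dup <- fpkm
  dup[, 2] <- dup[, 1]
  qc2 <- replicate_qc(dup, x$sim$samples)
  expect_equal(max(qc2$pairs$r), 1)
  # independent uniform noise: near-zero r, flagged
  noise <- matrix(stats::runif(1000 * 9), 1000, 9,
                  dimnames = list(sprintf("g%d", 1:1000),
                                  x$sim$samples$sample_id[1:9]))
  qc3 <- replicate_qc(noise, x$sim$samples[1:9, ])
  expect_lt(stats::median(abs(qc3$pairs$r)), 0.2)
  expect_true(all(qc3$pairs$flagged))
  # zero-variance vectors are flagged with a reason, not an error
  const <- noise
  const[, 1:3] <- 1
  qc4 <- replicate_qc(const, x$sim$samples[1:9, ])
  zv <- qc4$pairs[qc4$pairs$reason == "zero variance", ]
  expect_gt(nrow(zv), 0)
  expect_true(all(zv$flagged))
})

test_that("the QC threshold is a strict inequality", {
  x <- tiny_sim(n_genes = 50, tissues = "0-L")
  fpkm <- compute_fpkm(x$sim$counts[, 1:3], x$catalog)
  sheet <- x$sim$samples[1:3, ]
  r <- replicate_qc(fpkm, sheet)$pairs$r
  r0 <- min(r)
  flagged_at <- function(th) any(replicate_qc(fpkm, sheet,
                                              threshold = th)$pairs$flagged)
  expect_false(flagged_at(r0))          # r < r0 is false for the minimum
  expect_true(flagged_at(r0 + 1e-9))
})

test_that("gene catalogues round-trip through TSV and BED", {
  x <- tiny_sim(n_genes = 20, tissues = "0-L")
  tmp <- withr::local_tempdir()
  tsv <- file.path(tmp, "genes.tsv"); bed <- file.path(tmp, "genes.bed")
  write_gene_catalog(x$catalog, tsv, "tsv")
  write_gene_catalog(x$catalog, bed, "bed")
  from_tsv <- read_gene_catalog(tsv)
  expect_equal(from_tsv, x$catalog)
  from_bed <- read_gene_catalog(bed)
  m <- match(x$catalog$gene_id, from_bed$gene_id)
  expect_equal(from_bed$start[m], x$catalog$start)
  expect_equal(from_bed$end[m], x$catalog$end)
})

test_that("GFF3 gene features are read with 1-based coordinates", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t500\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t101\t500\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr2\tsrc\tgene\t1\t200\t.\t-\t.\tID=gB"), tmp)
  catalog <- read_gene_catalog(tmp, format = "gff3")
  expect_equal(nrow(catalog), 2)         # mRNA feature dropped
  expect_equal(catalog$start[catalog$gene_id == "gA"], 101)
  expect_equal(catalog$end[catalog$gene_id == "gA"], 500)
  expect_equal(catalog$length[catalog$gene_id == "gB"], 200)
})
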