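test_that("coverage reader applies the depth filter and recomputes percents", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c(
    "chr1\t100\t100\t50\t2\t2",   # depth 4 < 5 -> dropped
    "chr1\t200\t200\t100\t5\t0",  # depth 5 boundary -> kept
    "chr1\t300\t300\t40\t4\t6"),
    f)
  cov <- read_cov_table(f, min_depth = 5)
  expect_equal(cov$pos, c(200L, 300L))
  expect_equal(cov$percent, c(100, 40))
  expect_equal(cov$n_total, c(5L, 10L))
})

test_that("strand records at p and p+1 combine into one CpG", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t100\t60\t3\t2",
               "chr1\t101\t101\t40\t2\t3"), f)
  cov <- read_cov_table(f, min_depth = 5)
  expect_equal(nrow(cov), 1L)
  expect_equal(cov$pos, 100L)
  expect_equal(cov$n_meth, 5L)
  expect_equal(cov$n_total, 10L)
  expect_equal(cov$percent, 50)
  # exact assignment via genomic CpG sites gives the same answer
  sites <- list(chr1 = 100L)
  cov2 <- read_cov_table(f, min_depth = 5, cpg_sites = sites)
  expect_equal(cov2, cov)
})

test_that("malformed and inconsistent coverage records are reported", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("# header", "chr1\t100\t100\t50\t5\t5",
               "chr1\tnot_a_number\t?\t?\t?\t?"), f)
  expect_error(read_cov_table(f), "line 3")
  f2 <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\t100\t100\t90\t5\t5", f2) # stored 90 vs true 50
  expect_warning(cov <- read_cov_table(f2), "counts win")
  expect_equal(cov$percent, 50)
})

test_that("CpG tables round-trip through the coverage format exactly", {
  set.seed(11)
  for (i in 1:5) {
    cov <- methcompare:::new_cpg_table(data.table(
      chrom = sample(c("chr1", "chr2"), 30, TRUE),
      pos = sample(seq(10, 5000, by = 2), 30),
      n_meth = sample(0:8, 30, TRUE), n_total = 8L))
    f <- withr::local_tempfile(fileext = ".cov")
    write_cov_table(cov, f)
    # positions are already plus-strand CpGs two apart: no collapsing occurs
    back <- read_cov_table(f, min_depth = 1, collapse = FALSE)
    expect_equal(back, cov)
  }
})

test_that("strand combination is idempotent, conserves calls, and depth filtering is monotone", {
  set.seed(12)
  for (i in 1:10) {
    cov <- data.table(chrom = "chr1",
                      pos = sort(sample(1:400, 60)),
                      n_meth = sample(0:6, 60, TRUE))
    cov[, n_total := n_meth + sample(0:6, 60, TRUE)]
    cov <- cov[n_total > 0]
    once <- combine_strands(copy(cov))
    expect_equal(sum(once$n_total), sum(cov$n_total))
    twice <- combine_strands(copy(once))
    expect_equal(twice, once)
    sizes <- sapply(1:6, function(d) nrow(filter_depth(once, d)))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("read-level reader groups calls, drops sparse reads, splits mixed chromosomes", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "r1\t+\tchr1\t41\tZ",  # 4 calls out of order -> one ordered read
    "r1\t+\tchr1\t10\tZ",
    "r1\t-\tchr1\t35\tz",
    "r1\t+\tchr1\t20\tZ",
    "r2\t+\tchr1\t10\tZ",  # only 2 CpGs -> dropped
    "r2\t-\tchr1\t30\tz",
    "r3\t+\tchr1\t10\tZ",  # spans two chromosomes -> split, each part < 3
    "r3\t+\tchr1\t20\tZ",
    "r3\t+\tchr2\t10\tZ"), f)
  expect_warning(calls <- read_readlevel_calls(f, min_cpgs = 3),
                 "multiple chromosomes")
  expect_equal(unique(calls$read_id), "r1")
  expect_equal(calls$pos, c(10L, 20L, 35L, 41L))
  expect_equal(calls$state, c("M", "M", "U", "M"))
})

test_that("read calls survive a write/read round trip", {
  calls <- make_calls(list(
    ra = list(pos = c(10, 22, 40), states = "MMM"),
    rb = list(pos = c(100, 120, 130, 150), states = "MUMU")))
  f <- withr::local_tempfile(fileext = ".txt")
  write_read_calls(calls, f)
  back <- read_readlevel_calls(f, min_cpgs = 3)
  expect_equal(back[order(read_id, pos), .(read_id, chrom, pos, state)],
               calls[order(read_id, pos)])
})

test_that("annotation loading unifies GTF coordinates and merges isoforms", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t1001\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "gA_t1";',
    'chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "gA_t1";',
    'chr1\tsrc\ttranscript\t1501\t3000\t.\t+\t.\tgene_id "gA"; transcript_id "gA_t2";',
    'chr1\tsrc\texon\t1501\t3000\t.\t+\t.\tgene_id "gA"; transcript_id "gA_t2";'),
    f)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t500\t800", bed) # 0-based half-open on disk
  ann <- load_annotations(f, cgis = bed)
  expect_equal(ann$genes$start, 1001L)       # [1000, 3000) in 0-based terms
  expect_equal(ann$genes$end, 3000L)
  expect_equal(ann$genes$tss, 1001L)
  expect_equal(GenomicRanges::start(ann$cgis), 501L) # [500,800) -> 501..800
  expect_equal(GenomicRanges::end(ann$cgis), 800L)
})

test_that("annotations on chromosomes absent from the genome are skipped", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 250)))
  tx <- data.table(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                   chrom = c("chr1", "chrZ"), strand = "+",
                   start = c(101L, 11L), end = c(500L, 200L))
  expect_warning(ann <- load_annotations(tx, genome = genome),
                 "unknown chromosomes")
  expect_equal(ann$genes$gene_id, "g1")
  expect_equal(ann$chrom_lengths, c(chr1 = 1000L))
})
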