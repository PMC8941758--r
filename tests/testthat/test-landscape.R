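test_that("cpg_ratio matches hand-derived cases and conventions", {
  expect_equal(cpg_ratio("CGCG"), 2)
  expect_equal(cpg_ratio("ATATATAT"), 0)
  expect_equal(cpg_ratio("CCCC"), 0)      # degenerate denominator
  expect_equal(cpg_ratio("CGNNCG"), 2 * 4 / (2 * 2)) # N excluded everywhere
  expect_error(cpg_ratio(""), "empty")
})

test_that("cpg_ratio agrees with a brute-force counter on random sequences", {
  set.seed(21)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(5:80, 1), TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    expect_equal(cpg_ratio(s), oracle_cpg_ratio(s), label = s)
  }
})

test_that("sliding windows tile, estimate o/e near 1 on random sequence, drop N windows", {
  set.seed(22)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 60000, TRUE), collapse = "")))
  w <- sliding_cg_ratio(genome, window = 500L)
  expect_equal(w$start, seq(1L, 60000L - 499L, by = 500L))
  expect_lt(abs(mean(w$ratio) - 1), 0.05)
  genome_n <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("N", 400), paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                            collapse = ""))))
  wn <- sliding_cg_ratio(genome_n, window = 500L)
  expect_equal(wn$start, 501L) # first window is 80% N and dropped
})

test_that("methylation by CpG-ratio bin reduces to medians of window means", {
  set.seed(23)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")))
  w <- sliding_cg_ratio(genome)
  sites <- cpg_sites_from_genome(genome)$chr1
  cpg <- make_cpg(sites, percent = 80)
  mb <- methylation_by_cg_ratio(w, cpg)
  expect_true(all(mb[n_windows > 0, median_meth] == 80))
  expect_true(all(is.na(mb[n_windows == 0, median_meth])))
})

test_that("global mean methylation is the unweighted mean of percents", {
  expect_equal(global_mean_methylation(make_cpg(c(10, 20), c(0, 100))), 50)
  expect_equal(global_mean_methylation(make_cpg(c(10, 20, 30), c(100, 100, 40))), 80)
  expect_error(global_mean_methylation(make_cpg(integer(), numeric())), "empty")
})

test_that("CGI feature annotation follows the TSS > CDS > intron > intergenic precedence", {
  ann <- make_ann(
    data.table(transcript_id = "t1", gene_id = "g1", name = "g1",
               chrom = "chr1", strand = "+", start = 1000L, end = 9000L),
    exons = data.table(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
                       start = c(1000L, 4000L), end = c(1500L, 4500L)))
  cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(900, 4100, 2000, 20000), c(1100, 4300, 2500, 20400)))
  S4Vectors::mcols(cgis)$cgi_id <- paste0("c", 1:4)
  res <- annotate_cgi_features(cgis, ann)
  expect_equal(res$feature_class, c("promoter", "CDS", "intron", "intergenic"))
})

test_that("CGI methylation classes partition at 10 and 50 with the 35% coverage rule", {
  # 10 CpGs per CGI at positions 1..10, 101..110, 201..210, 301..310
  cgi <- data.table(chrom = "chr1",
                    start = c(1L, 101L, 201L, 301L),
                    end = c(20L, 120L, 220L, 320L),
                    cgi_id = paste0("c", 1:4), n_cpg = 10L)
  cpg <- make_cpg(c(1:10, 101:110, 201:210, 301:303),
                  c(rep(0, 10), rep(30, 10), rep(75, 10), rep(0, 3)))
  cls <- classify_cgi_methylation(cgi, cpg)
  expect_equal(cls$meth_class, c("unmethylated", "low", "high", NA))
  pr <- cgi_class_proportions(cls)
  expect_equal(sum(pr$percent), 100, tolerance = 1e-9)
  # exact boundaries: 10 -> low, 50 -> low, just above 50 -> high
  cgi2 <- data.table(chrom = "chr1", start = c(1L, 101L, 201L),
                     end = c(20L, 120L, 220L),
                     cgi_id = paste0("b", 1:3), n_cpg = 10L)
  cpg2 <- make_cpg(c(1:10, 101:110, 201:210),
                   c(rep(10, 10), rep(50, 10), rep(50.1, 10)), depth = 1000L)
  expect_equal(classify_cgi_methylation(cgi2, cpg2)$meth_class,
               c("low", "low", "high"))
})

test_that("promoters span [TSS-1000, TSS+500) strand-oriented and pick the densest TSS", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 4000)))
  ann <- make_ann(data.table(
    transcript_id = c("t1", "t2"), gene_id = c("gp", "gm"), name = c("gp", "gm"),
    chrom = "chr1", strand = c("+", "-"),
    start = c(5001L, 3001L), end = c(9000L, 5000L)))
  pr <- define_promoters(ann, genome)
  plus <- pr[gene_id == "gp"]
  expect_equal(c(plus$start, plus$end), c(4001L, 5500L)) # 0-based [4000,5500)
  minus <- pr[gene_id == "gm"]
  # TSS at 1-based 5000 is 0-based 4999: window [4499, 5999) mirrored
  expect_equal(c(minus$start, minus$end), c(4500L, 5999L))
  expect_equal(minus$end - minus$start + 1L, 1500L)
  expect_equal(plus$end - plus$start + 1L, 1500L)
})

test_that("with several TSS the promoter with the highest CpG ratio is kept", {
  # CG-rich around 2000, AT-rich around 6000
  s <- paste0(strrep("AT", 2000), strrep("CG", 500), strrep("AT", 4000))
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  ann <- make_ann(data.table(
    transcript_id = c("tA", "tB"), gene_id = "g1", name = "g1",
    chrom = "chr1", strand = "+", start = c(4500L, 8000L),
    end = c(9000L, 9000L)))
  pr <- define_promoters(ann, genome)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$tss, 4500L)
  # truncation at the contig start is flagged
  ann2 <- make_ann(data.table(transcript_id = "t", gene_id = "g2", name = "g2",
                              chrom = "chr1", strand = "+",
                              start = 500L, end = 4000L))
  expect_true(define_promoters(ann2, genome)$truncated)
})

test_that("promoter classes follow the ratio and GC gates and are total", {
  pr <- data.table(gene_id = c("a", "b", "c"),
                   cpg_ratio = c(0.8, 0.8, 0.1),
                   gc_percent = c(60, 50, 45))
  cls <- classify_promoters(pr, lower = 0.3, upper = 0.6)
  expect_equal(cls$class, c("HCP", "ICP", "LCP"))
  expect_error(classify_promoters(pr, lower = 0.6, upper = 0.3), "below")
  set.seed(24)
  rand <- data.table(gene_id = paste0("g", 1:200),
                     cpg_ratio = runif(200, 0, 1.2),
                     gc_percent = runif(200, 30, 70))
  cls2 <- classify_promoters(rand, 0.3, 0.6)
  expect_true(all(cls2$class %in% c("LCP", "ICP", "HCP")))
})

test_that("metaplot of a constant methylome is constant and respects strand", {
  genes <- data.table(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "-"), start = c(20001L, 60001L),
                      end = c(30000L, 70000L))
  genes[, tss := ifelse(strand == "+", start, end)]
  cpg <- make_cpg(seq(5001L, 85001L, by = 50L), 80)
  prof <- gene_metaplot(genes, cpg, chrx = NULL)
  expect_equal(nrow(prof), 40L)
  expect_true(all(prof$mean_meth == 80))
  # unmethylated stretch just downstream of each TSS shows up at body start
  pos <- seq(5001L, 85001L, by = 50L)
  pct <- rep(80, length(pos))
  pct[(pos >= 20001 & pos <= 21000) | (pos >= 69001 & pos <= 70000)] <- 0
  prof2 <- gene_metaplot(genes, make_cpg(pos, pct), chrx = NULL)
  expect_equal(which.min(prof2$mean_meth), 11L) # first body bin
})

test_that("gene-body methylation starts +500 bp after the TSS, strand-oriented", {
  genes <- data.table(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 1001L, end = 3000L, tss = 1001L)
  cpg <- make_cpg(c(1201L, 2501L), c(100, 50))
  expect_equal(gene_body_methylation(genes, cpg)$mean_meth, 50)
  gm <- data.table(gene_id = "g2", chrom = "chr1", strand = "-",
                   start = 1001L, end = 3000L, tss = 3000L)
  # mirrored: CpG at 2800 lies within 500 bp of the minus-strand TSS
  expect_equal(gene_body_methylation(gm, make_cpg(c(1201L, 2800L), c(100, 50)))$mean_meth,
               100)
  empty <- data.table(gene_id = "g3", chrom = "chr1", strand = "+",
                      start = 1001L, end = 3000L, tss = 1001L)
  expect_true(is.na(gene_body_methylation(empty, make_cpg(1100L, 50))$mean_meth))
})

test_that("feature stratification uses precedence and an independent TE layer", {
  ann <- make_ann(
    data.table(transcript_id = "t1", gene_id = "g1", name = "g1",
               chrom = "chr1", strand = "+", start = 5001L, end = 15000L),
    exons = data.table(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
                       start = 5001L, end = 5600L),
    repeats = GenomicRanges::GRanges("chr1", IRanges::IRanges(8000, 8500)))
  # CpG 5100: promoter+exon -> promoter; 8200: intron+TE -> intron & TE;
  # 30000: intergenic
  cpg <- make_cpg(c(5100L, 8200L, 30000L), c(10, 50, 90))
  fs <- feature_stratified_methylation(cpg, ann)
  expect_equal(fs[pos == 5100L, feature], "promoter")
  expect_setequal(fs[pos == 8200L, feature], c("intron", "TE"))
  expect_equal(fs[pos == 30000L, feature], "intergenic")
  ann$repeats <- GenomicRanges::GRanges()
  expect_false("TE" %in% feature_stratified_methylation(cpg, ann)$feature)
})
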