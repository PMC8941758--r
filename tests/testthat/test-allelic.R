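test_that("window statistics match hand-enumerated read mixtures", {
  cpgs <- c(110L, 120L, 130L)
  # 6 fully methylated + 6 fully unmethylated reads over one window
  reads <- c(
    setNames(lapply(1:6, function(i) list(pos = cpgs, states = "MMM")),
             paste0("m", 1:6)),
    setNames(lapply(1:6, function(i) list(pos = cpgs, states = "UUU")),
             paste0("u", 1:6)))
  calls <- make_calls(reads)
  cov <- make_cpg(cpgs, 50)
  st <- window_scan(calls, cov)
  w <- st[start == 101L]
  expect_equal(w$n_reads, 12L)
  expect_equal(w$mean_meth, 50)
  expect_equal(w$pct_full, 100)
  expect_equal(w$delta, 0)
  # mixed reads M,U,M: no fully called reads at all
  mixed <- make_calls(setNames(lapply(1:10, function(i)
    list(pos = cpgs, states = "MUM")), paste0("x", 1:10)))
  st2 <- window_scan(mixed, make_cpg(cpgs, 2 / 3 * 100))
  expect_true(all(st2$pct_full == 0))
  # 9 fully-M + 1 fully-U
  nine <- make_calls(c(
    setNames(lapply(1:9, function(i) list(pos = cpgs, states = "MMM")),
             paste0("m", 1:9)),
    list(u1 = list(pos = cpgs, states = "UUU"))))
  w3 <- window_scan(nine, make_cpg(cpgs, 90))[start == 101L]
  expect_equal(w3$pct_fully_m, 90)
  expect_equal(w3$pct_fully_u, 10)
  expect_equal(w3$delta, 80)
  expect_equal(w3$mean_meth, 90)
})

test_that("a read's fully-called status is judged over all its calls", {
  # read has M calls inside the window but a U call far outside
  calls <- make_calls(list(r1 = list(pos = c(110L, 120L, 900L),
                                     states = "MMU"),
                           r2 = list(pos = c(110L, 120L, 130L),
                                     states = "MMM"),
                           r3 = list(pos = c(112L, 124L, 133L),
                                     states = "MMM"),
                           r4 = list(pos = c(111L, 125L, 131L),
                                     states = "MMM"),
                           r5 = list(pos = c(113L, 126L, 132L),
                                     states = "MMM")))
  st <- window_scan(calls, make_cpg(c(110L, 120L, 130L), 80))
  w <- st[start == 101L]
  expect_equal(w$n_reads, 5L)
  expect_equal(w$n_fully_m, 4L) # r1 is not fully methylated
  expect_false(w$low_reads)
})

test_that("window filtering applies the allelic gates exactly", {
  mk <- function(mean_meth, pct_full, delta, n_reads = 10L) {
    pm <- (pct_full + delta) / 2
    data.table(chrom = "chr1", start = 1L, end = 50L, n_reads = n_reads,
               n_fully_m = 0L, n_fully_u = 0L, pct_fully_m = pm,
               pct_fully_u = pct_full - pm, pct_full = pct_full,
               delta = delta, mean_meth = mean_meth, n_cpg = 3L,
               low_reads = n_reads < 5L)
  }
  expect_equal(nrow(filter_windows(mk(50, 100, 0))), 1L)   # all gates pass
  expect_equal(nrow(filter_windows(mk(90, 100, 80))), 0L)  # mean + delta fail
  expect_equal(nrow(filter_windows(mk(45, 85, 10))), 0L)   # pct_full fails
  expect_equal(nrow(filter_windows(mk(45, 90, 10))), 0L)   # strict >90
  expect_equal(nrow(filter_windows(mk(45, 95, 40))), 0L)   # strict <40
  expect_equal(nrow(filter_windows(mk(30, 95, 39))), 1L)   # inclusive mean
  expect_equal(nrow(filter_windows(mk(60, 95, 39))), 1L)
  expect_equal(nrow(filter_windows(mk(50, 100, 0, n_reads = 4L))), 0L)
})

test_that("window merging unions overlapping or scan-adjacent windows", {
  mk_pass <- function(starts) data.table(
    chrom = "chr1", start = starts, end = starts + 49L, n_reads = 10L,
    n_fully_m = 5L, n_fully_u = 5L, pct_fully_m = 50, pct_fully_u = 50,
    pct_full = 100, delta = 0, mean_meth = 50, n_cpg = 3L, low_reads = FALSE)
  cov <- make_cpg(seq(100L, 400L, by = 10L), 50)
  m1 <- merge_windows(mk_pass(c(100L, 110L, 120L)), cov)
  expect_equal(nrow(m1), 1L)
  expect_equal(c(m1$start, m1$end), c(100L, 169L)) # [100, 170) span
  m2 <- merge_windows(mk_pass(c(100L, 250L)), cov)
  expect_equal(nrow(m2), 2L)
  m3 <- merge_windows(mk_pass(100L), cov)
  expect_equal(c(m3$start, m3$end, m3$size_bp), c(100L, 149L, 50L))
  expect_equal(m3$n_cpg, 5L) # CpGs at 100,110,...,140
  # idempotence and order independence
  shuffled <- mk_pass(c(120L, 100L, 300L, 110L))
  expect_equal(merge_windows(shuffled, cov),
               merge_windows(shuffled[c(2, 4, 1, 3)], cov))
})

test_that("mode filters drop chrX and excluded regions, then gate by size and CpGs", {
  cand <- data.table(
    chrom = c("chr1", "chr1", "chrX", "chr2"),
    start = c(1000L, 5000L, 1000L, 9000L),
    end = c(1399L, 5360L, 1500L, 9500L),
    size_bp = c(400L, 361L, 501L, 501L),
    n_windows = 5L, n_cpg = c(19L, 22L, 30L, 25L), mean_meth = 45)
  chroms <- c("chr1", "chr2", "chrX")
  strict <- apply_mode_filters(cand, "stringent", chrx_name = "chrX",
                               chrom_names = chroms)
  lenient <- apply_mode_filters(cand, "lenient", chrx_name = "chrX",
                                chrom_names = chroms)
  expect_equal(strict$start, c(5000L, 9000L))  # 19-CpG region fails stringent
  expect_equal(lenient$start, c(1000L, 5000L, 9000L))
  expect_true(all(strict$start %in% lenient$start)) # stringent within lenient
  excl <- GenomicRanges::GRanges("chr2", IRanges::IRanges(9400L, 9600L))
  strict2 <- apply_mode_filters(cand, "stringent", exclusions = excl,
                                chrx_name = "chrX", chrom_names = chroms)
  expect_equal(strict2$start, 5000L)
  expect_error(apply_mode_filters(cand, "stringent", chrx_name = "X",
                                  chrom_names = chroms), "unknown X")
  # the 350-bp size gate is strict
  border <- data.table(chrom = "chr1", start = 1L, end = 350L, size_bp = 350L,
                       n_windows = 3L, n_cpg = 30L, mean_meth = 45)
  expect_equal(nrow(apply_mode_filters(border, "stringent", chrx_name = "chrX",
                                       chrom_names = chroms)), 0L)
})

test_that("stringent calls are a subset of lenient calls on random candidates", {
  set.seed(41)
  for (i in 1:10) {
    cand <- data.table(chrom = sample(c("chr1", "chr2", "chrX"), 30, TRUE),
                       start = sample.int(1e5, 30))
    cand[, `:=`(end = start + sample(50:1000, 30, TRUE))]
    cand[, `:=`(size_bp = end - start + 1L, n_windows = 2L,
                n_cpg = sample(5:40, 30, TRUE), mean_meth = 45)]
    s <- apply_mode_filters(cand, "stringent", chrx_name = "chrX")
    l <- apply_mode_filters(cand, "lenient", chrx_name = "chrX")
    expect_true(all(paste(s$chrom, s$start) %in% paste(l$chrom, l$start)))
  }
})

test_that("DMRs are associated with the nearest gene within the distance cap", {
  genes <- data.table(gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
                      start = c(10000L, 200000L), end = c(20000L, 210000L))
  genes[, tss := start]
  dmr <- data.table(chrom = "chr1",
                    start = c(15000L, 30000L, 100000L),
                    end = c(15400L, 30400L, 100400L))
  got <- associate_genes(dmr, genes)
  expect_equal(got$nearest_gene, c("gA", "gA", NA))
  expect_equal(got$distance_bp[1:2], c(0L, 9999L))
})

test_that("cross-species aggregation counts species and ranks stringent calls", {
  om <- data.table(species = rep(c("s1", "s2", "s3"), each = 2),
                   gene_id = paste0(rep(c("s1", "s2", "s3"), each = 2),
                                    "_", c("a", "b")),
                   ortholog = rep(c("ogA", "ogB"), 3))
  per <- list(
    s1 = data.table(nearest_gene = c("s1_a", "s1_b"),
                    mode = c("stringent", "lenient")),
    s2 = data.table(nearest_gene = c("s2_a"), mode = "stringent"),
    s3 = data.table(nearest_gene = c("s3_a"), mode = "lenient"))
  got <- cross_species_dmr_genes(per, om, min_species = 2)
  expect_equal(got$ortholog, "ogA")
  expect_equal(got$n_species, 3L)
  expect_equal(got$n_stringent, 2L)
  expect_equal(nrow(cross_species_dmr_genes(per, om, min_species = 4)), 0L)
  expect_warning(empty <- cross_species_dmr_genes(per, om[0], 2), "empty")
  expect_equal(nrow(empty), 0L)
})
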