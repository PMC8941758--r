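test_that("UMR detection recovers hand-constructed runs", {
  # 10 consecutive CpGs at 0% flanked by 90%: one UMR spanning exactly the 10
  pos <- seq(100L, by = 50L, length.out = 24L)
  pct <- c(rep(90, 7), rep(0, 10), rep(90, 7))
  umr <- detect_umrs(make_cpg(pos, pct))
  expect_equal(length(umr), 1L)
  expect_equal(GenomicRanges::start(umr), pos[8])
  expect_equal(GenomicRanges::end(umr), pos[17])
  expect_equal(S4Vectors::mcols(umr)$n_cpg, 10L)
  # 4 consecutive CpGs at 0%: below nCpG.cutoff = 5, no UMR
  pct4 <- c(rep(90, 10), rep(0, 4), rep(90, 10))
  expect_equal(length(detect_umrs(make_cpg(pos, pct4))), 0L)
  # uniformly methylated: nothing
  expect_equal(length(detect_umrs(make_cpg(pos, rep(80, 24)))), 0L)
})

test_that("UMR detection equals the brute-force run-enumeration oracle", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(20:200, 1)
    pos <- cumsum(sample(2:300, n, TRUE))
    pct <- ifelse(runif(n) < 0.4, runif(n, 0, 15), runif(n, 60, 100))
    cpgt <- make_cpg(pos, pct)
    if (smoothing_tie(cpgt$percent)) next
    got <- methcompare:::gr_to_dt(detect_umrs(cpgt))
    want <- oracle_umrs(cpgt$pos, cpgt$percent)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_cpg, want$n_cpg)
    }
  }
})

test_that("masked PMD CpGs are excluded and never bridged", {
  pos <- seq(100L, by = 50L, length.out = 30L)
  pct <- c(rep(0, 10), rep(50, 10), rep(0, 10)) # middle block intermediate
  pmd <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos[11], pos[20]))
  umr <- detect_umrs(make_cpg(pos, pct), pmds = pmd, smooth_k = 1L)
  expect_equal(length(umr), 2L) # the masked CpGs split the low run
  expect_equal(GenomicRanges::start(umr), c(pos[1], pos[21]))
})

test_that("DMVs are UMRs at least 5 kb long, inclusive, monotone in the threshold", {
  mk <- function(width) GenomicRanges::GRanges("chr1",
    IRanges::IRanges(1000L, 1000L + width - 1L), n_cpg = 10L, mean_meth = 1)
  umrs <- c(mk(4999L), mk(5000L), mk(6000L))
  expect_equal(GenomicRanges::width(call_dmvs(umrs)), c(5000L, 6000L))
  expect_equal(length(call_dmvs(GenomicRanges::GRanges())), 0L)
  counts <- vapply(c(1000L, 3000L, 5000L, 6001L, 10000L),
                   function(th) length(call_dmvs(umrs, th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("PMD approximation ignores bimodal methylomes and impossible cutoffs", {
  set.seed(32)
  pos <- cumsum(sample(30:80, 400, TRUE))
  pct <- ifelse(runif(400) < 0.5, runif(400, 0, 9), runif(400, 91, 100))
  expect_equal(length(suppressWarnings(detect_pmds(make_cpg(pos, pct)))), 0L)
  inter <- make_cpg(pos, runif(400, 40, 60))
  expect_equal(length(detect_pmds(inter, frac_cutoff = 1.01)), 0L)
  expect_warning(detect_pmds(make_cpg(pos[1:50], pct[1:50])), "fewer than")
})

test_that("implanted random-partial domains are recovered with high overlap", {
  sp <- small_species(seed = 6, spec = small_spec(6, depth = 20))
  cov <- filter_depth(sp$cov, 5)
  pmds <- suppressWarnings(detect_pmds(cov))
  tr <- sp$truth$pmds
  got <- methcompare:::gr_to_dt(pmds)
  jac <- vapply(seq_len(nrow(tr)), function(i) {
    d <- got[chrom == tr$chrom[i] & start <= tr$end[i] & end >= tr$start[i]]
    if (!nrow(d)) return(0)
    ov <- sum(pmin(d$end, tr$end[i]) - pmax(d$start, tr$start[i]) + 1)
    un <- max(d$end, tr$end[i]) - min(d$start, tr$start[i]) + 1
    ov / un
  }, numeric(1))
  expect_true(all(jac > 0.8))
})

test_that("DMV-gene overlap uses the any-overlap rule", {
  genes <- data.table(gene_id = c("in", "edge", "out"), chrom = "chr1",
                      strand = "+", start = c(2000L, 900L, 20000L),
                      end = c(3000L, 1000L, 30000L))
  genes[, tss := start]
  dmv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000L, 8000L))
  expect_setequal(dmv_gene_overlap(dmv, genes), c("in", "edge"))
  expect_equal(dmv_gene_overlap(GenomicRanges::GRanges(), genes), character())
})

test_that("conservation percent implements 100*n/min(x, y)", {
  map <- data.table(gene_id = c(paste0("a", 1:9), paste0("b", 1:9)),
                    ortholog = rep(paste0("og", 1:9), 2))
  expect_equal(as.numeric(conservation_percent(paste0("a", 1:7),
                                               paste0("b", 1:7), map)), 100)
  expect_equal(as.numeric(conservation_percent(paste0("a", 1:4),
                                               paste0("b", 5:7), map)), 0)
  got <- conservation_percent(paste0("a", 1:4), c("b1", "b2", "b9"), map)
  expect_equal(as.numeric(got), 100 * 2 / 3)
  # symmetry, containment, bounds, unmapped counting
  expect_equal(as.numeric(conservation_percent(c("b1", "b2", "b9"),
                                               paste0("a", 1:4), map)),
               as.numeric(got))
  expect_equal(as.numeric(conservation_percent(paste0("a", 1:3),
                                               paste0("b", 1:9), map)), 100)
  expect_true(is.na(conservation_percent(character(), "b1", map)))
  expect_equal(attr(conservation_percent(c("a1", "zz"), "b1", map),
                    "n_unmapped"), 1L)
  set.seed(33)
  for (i in 1:20) {
    a <- sample(paste0("a", 1:9), sample(1:9, 1))
    b <- sample(paste0("b", 1:9), sample(1:9, 1))
    v <- as.numeric(conservation_percent(a, b, map))
    expect_true(v >= 0 && v <= 100)
  }
})
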