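library(data.table)

# CpG table from positions and percents at a given uniform depth
make_cpg <- function(pos, percent, chrom = "chr1", depth = 10L) {
  n_meth <- as.integer(round(percent / 100 * depth))
  methcompare:::new_cpg_table(data.table(
    chrom = chrom, pos = as.integer(pos), n_meth = n_meth, n_total = depth))
}

# read-call table from a list of per-read M/U strings at given positions
make_calls <- function(reads, chrom = "chr1") {
  rbindlist(lapply(names(reads), function(id) {
    r <- reads[[id]]
    data.table(read_id = id, chrom = chrom, pos = as.integer(r$pos),
               state = strsplit(r$states, "")[[1]])
  }))
}

# minimal annotation bundle from a transcripts table (+ optional parts)
make_ann <- function(tx, exons = NULL, cgis = NULL, repeats = NULL) {
  tx <- as.data.table(tx)
  tx[, tss := ifelse(strand == "+", start, end)]
  list(genes = methcompare:::build_gene_models(tx), transcripts = tx,
       exons = if (!is.null(exons)) as.data.table(exons) else
         data.table(gene_id = character(), transcript_id = character(),
                    chrom = character(), start = integer(), end = integer()),
       cgis = if (!is.null(cgis)) cgis else GenomicRanges::GRanges(),
       repeats = if (!is.null(repeats)) repeats else GenomicRanges::GRanges(),
       exclusions = GenomicRanges::GRanges(),
       chrom_lengths = NULL, cpg_sites = NULL)
}

# small but complete simulated species (fast; used by several module tests)
small_spec <- function(seed = 1L, ...) {
  methylome_spec(seed = seed, n_imprinted = 2L, n_valleys = 1L,
                 n_germline = 1L, n_meth_promoter_bg = 1L, n_escapees = 1L,
                 ...)
}

small_species <- function(seed = 1L, spec = small_spec(seed), ...) {
  simulate_species("t1", seed = seed, spec = spec,
                   n_chrom = 2L, chrom_len = c(500000L, 250000L),
                   gene_density = 1.2, ...)
}

# the reference study at the canonical seed, simulated and analysed once
# per test run (parameter-recovery checks share it)
.study_cache <- new.env(parent = emptyenv())
default_study <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(.study_cache[[key]])) {
    cfg <- default_config(seed = seed)
    study <- simulate_study(n_species = cfg$n_species, seed = cfg$seed,
                            spec = cfg$methylome)
    for (sp in names(study$species)) {
      b <- study$species[[sp]]
      study$species[[sp]]$annotations$exclusions <-
        methcompare:::dt_to_gr(
          b$annotations$genes[gene_id %in% b$truth$valleys$gene_id])
    }
    results <- lapply(study$species, run_species_stages, config = cfg)
    .study_cache[[key]] <- list(cfg = cfg, study = study, results = results)
  }
  .study_cache[[key]]
}

# brute-force observed/expected CpG-ratio oracle (character loop)
oracle_cpg_ratio <- function(s) {
  ch <- strsplit(s, "")[[1]]
  keep <- ch %in% c("A", "C", "G", "T")
  n_c <- sum(ch == "C"); n_g <- sum(ch == "G")
  n_cg <- 0L
  for (i in seq_len(length(ch) - 1L)) {
    if (ch[i] == "C" && ch[i + 1L] == "G") n_cg <- n_cg + 1L
  }
  if (n_c * n_g == 0) return(0)
  n_cg * sum(keep) / (n_c * n_g)
}

# brute-force UMR oracle: explicit smoothing + run scan, no shared code
oracle_umrs <- function(pos, percent, meth_cutoff = 0.5, n_cpg_cutoff = 5L,
                        smooth_k = 3L) {
  n <- length(pos)
  h <- (smooth_k - 1L) %/% 2L
  sm <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - h):min(n, i + h)
    sm[i] <- mean(percent[idx] / 100)
  }
  below <- sm < meth_cutoff
  out <- list(); i <- 1L
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1L]) j <- j + 1L
      if (j - i + 1L >= n_cpg_cutoff) {
        out[[length(out) + 1L]] <- c(start = pos[i], end = pos[j],
                                     n_cpg = j - i + 1L)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out)) {
    return(data.table(start = integer(), end = integer(), n_cpg = integer()))
  }
  as.data.table(do.call(rbind, out))
}

# TRUE when a smoothed value sits numerically on the 0.5 cutoff (such
# cases are representation-dependent and excluded from oracle comparisons)
smoothing_tie <- function(percent, k = 3L) {
  n <- length(percent)
  h <- (k - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    mean(percent[max(1L, i - h):min(n, i + h)] / 100)
  }, numeric(1))
  any(abs(sm - 0.5) < 1e-9)
}

# reciprocal overlap of one truth interval with the best-matching call
best_reciprocal_overlap <- function(truth_row, calls_dt) {
  d <- calls_dt[chrom == truth_row$chrom & start <= truth_row$end &
                  end >= truth_row$start]
  if (!nrow(d)) return(0)
  max(vapply(seq_len(nrow(d)), function(j) {
    ov <- min(d$end[j], truth_row$end) - max(d$start[j], truth_row$start) + 1
    min(ov / (truth_row$end - truth_row$start + 1),
        ov / (d$end[j] - d$start[j] + 1))
  }, numeric(1)))
}

overlaps_truth <- function(calls_dt, truth_dt) {
  vapply(seq_len(nrow(truth_dt)), function(i) {
    calls_dt[chrom == truth_dt$chrom[i] & start <= truth_dt$end[i] &
               end >= truth_dt$start[i], .N] > 0
  }, logical(1))
}
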