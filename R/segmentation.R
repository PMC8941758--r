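# Methylome segmentation: partially methylated domains (documented
# windowed approximation), unmethylated regions with meth.cutoff = 0.5 and
# nCpG.cutoff = 5, DNA methylation valleys (UMRs >= 5 kb), and
# cross-species conservation of valley genes.

#' Detect partially methylated domains (windowed approximation)
#'
#' A deliberately transparent stand-in for HMM-based PMD segmentation: for
#' every CpG, the fraction of CpGs in a centred `win_cpgs` window whose
#' methylation lies in the intermediate band is computed; maximal runs of
#' CpGs where this fraction exceeds `frac_cutoff` are expanded to the span
#' of their windows, merged across gaps up to `merge_gap_bp`, and snapped to
#' the first/last CpG. Externally supplied PMD intervals can be passed
#' downstream instead (see [detect_umrs()]).
#'
#' @param cpg depth-filtered CpG table
#' @param win_cpgs window size in CpGs (odd)
#' @param intermediate_band methylation fraction band counted as
#'   intermediate (inclusive)
#' @param frac_cutoff minimum fraction of intermediate CpGs in the window
#' @param merge_gap_bp merge flagged intervals separated by at most this gap
#' @param min_size_bp drop merged intervals below this size (PMDs are large
#'   domains; this keeps isolated ~50%-methylated CpG islands out)
#' @return GRanges of PMD intervals with n_cpg and mean_meth
#' @export
detect_pmds <- function(cpg, win_cpgs = 101L, intermediate_band = c(0.3, 0.7),
                        frac_cutoff = 0.5, merge_gap_bp = 5000L,
                        min_size_bp = 10000L) {
  h <- (win_cpgs - 1L) %/% 2L
  out <- lapply(split(cpg, cpg$chrom), function(d) {
    data.table::setorder(d, pos)
    if (nrow(d) < win_cpgs) {
      warning(sprintf("chromosome %s has fewer than %d CpGs; no PMD call",
                      d$chrom[1L], win_cpgs))
      return(NULL)
    }
    x <- d$percent / 100
    inter <- as.numeric(x >= intermediate_band[1] & x <= intermediate_band[2])
    frac <- smooth_partial(inter, win_cpgs)
    runs <- true_runs(frac > frac_cutoff)
    if (nrow(runs) == 0L) return(NULL)
    n <- nrow(d)
    runs[, `:=`(start = d$pos[pmax(from - h, 1L)],
                end = d$pos[pmin(to + h, n)])]
    gr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(d$chrom[1L], IRanges::IRanges(runs$start, runs$end)),
      min.gapwidth = merge_gap_bp)
    gr
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(GenomicRanges::GRanges())
  gr <- sort(do.call(c, unname(out)))
  gr <- gr[GenomicRanges::width(gr) >= min_size_bp]
  dt <- region_mean_methylation(gr, cpg)
  S4Vectors::mcols(gr)$n_cpg <- dt$n_covered
  S4Vectors::mcols(gr)$mean_meth <- dt$mean_meth
  gr
}

#' Detect unmethylated regions (UMRs)
#'
#' Maximal runs of at least `n_cpg_cutoff` consecutive CpGs whose smoothed
#' methylation fraction (centred `smooth_k`-CpG rolling mean, partial at the
#' edges) is below `meth_cutoff`. CpGs inside PMDs are masked first and
#' runs never bridge a masked CpG. Intervals span the first to the last CpG
#' of the qualifying run.
#'
#' @param cpg depth-filtered CpG table
#' @param pmds GRanges of PMDs to mask (e.g. from [detect_pmds()] or an
#'   external BED), or NULL
#' @param meth_cutoff methylation fraction cutoff (default 0.5)
#' @param n_cpg_cutoff minimum CpGs per region (default 5)
#' @param smooth_k smoothing window in CpGs (1 disables smoothing)
#' @return GRanges of UMRs with n_cpg and mean_meth
#' @export
detect_umrs <- function(cpg, pmds = NULL, meth_cutoff = 0.5,
                        n_cpg_cutoff = 5L, smooth_k = 3L) {
  cpg <- data.table::as.data.table(cpg)
  masked <- if (!is.null(pmds) && length(pmds)) {
    IRanges::overlapsAny(cpg_gr(cpg), pmds)
  } else rep(FALSE, nrow(cpg))
  out <- lapply(split(data.table::data.table(cpg, masked = masked), cpg$chrom),
                function(d) {
    data.table::setorder(d, pos)
    res <- list()
    for (seg in split(d[!(masked)], cumsum(d$masked)[!d$masked])) {
      if (nrow(seg) < n_cpg_cutoff) next
      sm <- smooth_partial(seg$percent / 100, smooth_k)
      runs <- true_runs(sm < meth_cutoff)
      runs <- runs[to - from + 1L >= n_cpg_cutoff]
      if (nrow(runs)) {
        res[[length(res) + 1L]] <- data.table::data.table(
          chrom = seg$chrom[1L], start = seg$pos[runs$from],
          end = seg$pos[runs$to],
          n_cpg = runs$to - runs$from + 1L,
          mean_meth = vapply(seq_len(nrow(runs)), function(i) {
            mean(seg$percent[runs$from[i]:runs$to[i]])
          }, numeric(1)))
      }
    }
    data.table::rbindlist(res)
  })
  dt <- data.table::rbindlist(out[!vapply(out, is.null, TRUE)])
  if (!nrow(dt)) return(GenomicRanges::GRanges())
  sort(dt_to_gr(dt, keep = c("n_cpg", "mean_meth")))
}

#' Call DNA methylation valleys
#'
#' DMVs are UMRs with a size >= `min_size_bp` (inclusive, default 5000 bp).
#' @param umrs GRanges from [detect_umrs()]
#' @param min_size_bp inclusive size threshold
#' @return GRanges subset
#' @export
call_dmvs <- function(umrs, min_size_bp = 5000L) {
  umrs[GenomicRanges::width(umrs) >= min_size_bp]
}

#' Genes overlapping DMVs
#'
#' Any overlap (>= 1 bp) between the isoform-merged gene body and a DMV.
#' @param dmvs GRanges
#' @param genes gene table
#' @return character vector of gene ids
#' @export
dmv_gene_overlap <- function(dmvs, genes) {
  if (!length(dmvs) || nrow(genes) == 0L) return(character())
  hit <- IRanges::overlapsAny(genes_gr(genes), dmvs)
  genes$gene_id[hit]
}

#' Cross-species conservation percentage of two gene sets
#'
#' 100 * n / min(x, y), where n is the number of shared orthologs and x, y
#' the mapped set sizes. Genes absent from the ortholog map are dropped and
#' counted in the `n_unmapped` attribute.
#'
#' @param genes_a,genes_b character vectors of gene ids
#' @param ortholog_map data.table(gene_id, ortholog) covering both species
#' @return percent in [0, 100]; NA if either mapped set is empty
#' @export
conservation_percent <- function(genes_a, genes_b, ortholog_map) {
  om <- data.table::as.data.table(ortholog_map)
  map <- function(g) unique(om$ortholog[om$gene_id %in% g])
  a <- map(genes_a); b <- map(genes_b)
  n_unmapped <- sum(!genes_a %in% om$gene_id) + sum(!genes_b %in% om$gene_id)
  if (!length(a) || !length(b)) {
    res <- NA_real_
  } else {
    res <- 100 * length(intersect(a, b)) / min(length(a), length(b))
  }
  attr(res, "n_unmapped") <- n_unmapped
  res
}

#' Pairwise DMV-gene conservation matrix
#'
#' @param dmv_genes named list (per species) of gene-id vectors
#' @param ortholog_map data.table(species, gene_id, ortholog)
#' @return numeric matrix of conservation percents (100 on the diagonal)
#' @export
conservation_matrix <- function(dmv_genes, ortholog_map) {
  sp <- names(dmv_genes)
  m <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in sp) for (j in sp) {
    m[i, j] <- as.numeric(conservation_percent(
      dmv_genes[[i]], dmv_genes[[j]],
      ortholog_map[species %in% c(i, j), .(gene_id, ortholog)]))
  }
  m
}
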