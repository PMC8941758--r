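# X-vs-autosome methylation contrasts and prediction of genes escaping
# X-chromosome inactivation from promoter-CGI methylation.

#' Promoter-CGI methylation of every gene
#'
#' A gene's promoter CGI is the CGI overlapping one of its transcript TSS;
#' its mean methylation follows the covered-CpG rule (35% of the CGI's
#' CpGs must be covered, otherwise NA).
#'
#' @param ann annotation bundle (genes, transcripts, cgis with n_cpg)
#' @param cpg depth-filtered CpG table
#' @param min_covered_fraction coverage rule threshold
#' @return data.table(gene_id, ortholog?, chrom, start, end, n_cpg,
#'   mean_meth, covered_frac)
#' @export
promoter_cgi_methylation <- function(ann, cpg, min_covered_fraction = 0.35) {
  tssg <- GenomicRanges::GRanges(ann$transcripts$chrom,
                                 IRanges::IRanges(ann$transcripts$tss, ann$transcripts$tss))
  hit <- GenomicRanges::findOverlaps(ann$cgis, tssg)
  qi <- unique(S4Vectors::queryHits(hit))
  pc <- ann$cgis[qi]
  # gene owning each promoter CGI: the gene of the first overlapping TSS
  first_hit <- S4Vectors::subjectHits(hit)[match(qi, S4Vectors::queryHits(hit))]
  dt <- gr_to_dt(pc)
  dt[, gene_id := ann$transcripts$gene_id[first_hit]]
  g <- ann$genes
  if (!is.null(g$ortholog)) {
    dt <- merge(dt, g[, .(gene_id, ortholog)], by = "gene_id", all.x = TRUE)
  }
  dt <- region_mean_methylation(dt, cpg)
  dt[, covered_frac := ifelse(n_cpg > 0, n_covered / n_cpg, NA_real_)]
  dt[is.na(covered_frac) | covered_frac < min_covered_fraction,
     mean_meth := NA_real_]
  dt[]
}

#' Compare promoter-CGI methylation on X vs autosomes
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) on per-CGI mean methylation.
#'
#' @param pcgi output of [promoter_cgi_methylation()]
#' @param chrx_name X chromosome name
#' @return list(x, autosome, p_value, median_x, median_autosome)
#' @export
x_vs_autosome_pcgi <- function(pcgi, chrx_name = "chrX") {
  d <- pcgi[!is.na(mean_meth)]
  xs <- d[chrom == chrx_name, mean_meth]
  as_ <- d[chrom != chrx_name, mean_meth]
  p <- if (length(xs) && length(as_)) {
    suppressWarnings(stats::wilcox.test(xs, as_, exact = FALSE)$p.value)
  } else NA_real_
  list(x = xs, autosome = as_, p_value = p,
       median_x = stats::median(xs), median_autosome = stats::median(as_))
}

#' Compare non-CGI background methylation on X vs autosomes
#'
#' Non-overlapping 1-kb genomic tiles fully contained in their chromosome;
#' tiles overlapping a CGI by even 1 bp are excluded; tiles contribute the
#' unweighted mean over their covered CpGs (>= 1 required).
#'
#' @param cpg CpG table
#' @param cgis GRanges of CpG islands
#' @param chrom_lengths named integer vector
#' @param tile_bp tile width (default 1000)
#' @param chrx_name X chromosome name
#' @return list(x, autosome, p_value, median_x, median_autosome, tiles)
#' @export
x_vs_autosome_tiles <- function(cpg, cgis, chrom_lengths, tile_bp = 1000L,
                                chrx_name = "chrX") {
  tiles <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    n <- chrom_lengths[[ch]] %/% tile_bp
    if (n == 0L) return(NULL)
    data.table::data.table(chrom = ch,
                           start = (seq_len(n) - 1L) * tile_bp + 1L,
                           end = seq_len(n) * tile_bp)
  }))
  if (length(cgis)) {
    tiles <- tiles[!IRanges::overlapsAny(dt_to_gr(tiles), cgis)]
  }
  tiles <- region_mean_methylation(tiles, cpg)
  tiles <- tiles[n_covered >= 1L]
  xs <- tiles[chrom == chrx_name, mean_meth]
  as_ <- tiles[chrom != chrx_name, mean_meth]
  p <- if (length(xs) && length(as_)) {
    suppressWarnings(stats::wilcox.test(xs, as_, exact = FALSE)$p.value)
  } else NA_real_
  list(x = xs, autosome = as_, p_value = p,
       median_x = stats::median(xs), median_autosome = stats::median(as_),
       tiles = tiles)
}

#' Predict XCI escapees from promoter-CGI methylation
#'
#' An X-linked gene with an unmethylated promoter CGI (mean methylation
#' strictly below `threshold`, default 10%) is predicted to escape X
#' inactivation; genes whose pCGI fails the coverage rule are not callable.
#'
#' @param pcgi output of [promoter_cgi_methylation()]
#' @param chrx_name X chromosome name
#' @param threshold strict percent threshold
#' @return data.table(gene_id, ortholog?, pcgi_mean_meth, is_escapee)
#' @export
call_escapees <- function(pcgi, chrx_name = "chrX", threshold = 10) {
  d <- pcgi[chrom == chrx_name & !is.na(mean_meth)]
  d[, is_escapee := mean_meth < threshold]
  cols <- intersect(c("gene_id", "ortholog"), names(d))
  d[, c(cols, "mean_meth", "is_escapee"), with = FALSE][
    , data.table::setnames(.SD, "mean_meth", "pcgi_mean_meth")]
}

#' Genes escaping XCI in several species
#'
#' @param per_species named list (per species) of [call_escapees()] tables
#' @param ortholog_map data.table(species, gene_id, ortholog)
#' @param min_species minimum number of species (default 3)
#' @return data.table(ortholog, n_species, species)
#' @export
cross_species_escapees <- function(per_species, ortholog_map,
                                   min_species = 3L) {
  om <- data.table::as.data.table(ortholog_map)
  rows <- data.table::rbindlist(lapply(names(per_species), function(sp) {
    d <- per_species[[sp]]
    d <- d[is_escapee == TRUE]
    if (nrow(d) == 0L) return(NULL)
    if (is.null(d$ortholog)) {
      d <- merge(d, om[species == sp, .(gene_id, ortholog)], by = "gene_id")
    }
    unique(d[!is.na(ortholog), .(ortholog)])[, species := sp]
  }))
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.table::data.table(ortholog = character(),
                                  n_species = integer(), species = character()))
  }
  res <- rows[, .(n_species = .N,
                  species = paste(sort(species), collapse = ",")),
              by = ortholog]
  res <- res[n_species >= min_species]
  data.table::setorder(res, -n_species, ortholog)
  res[]
}
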