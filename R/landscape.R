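# Genome-scale CpG-density and methylation statistics: observed/expected
# CpG-ratio windows, global means, CGI and promoter classification,
# gene metaplots and feature-stratified methylation.

#' Observed/expected CpG ratio of a sequence
#'
#' ratio = (number of CpGs x number of bp) / (number of Cs x number of Gs).
#' N bases are excluded from all counts and from the length; the ratio is 0
#' by convention when the denominator is 0.
#'
#' @param seq a DNAString or single character string (A/C/G/T/N)
#' @return numeric ratio >= 0
#' @export
cpg_ratio <- function(seq) {
  if (is.character(seq)) {
    stopifnot(length(seq) == 1L)
    seq <- Biostrings::DNAString(seq)
  }
  if (length(seq) == 0L) stop("empty sequence")
  f <- Biostrings::letterFrequency(seq, c("C", "G", "N"))
  len <- length(seq) - f[["N"]]
  n_cg <- Biostrings::countPattern("CG", seq)
  denom <- f[["C"]] * f[["G"]]
  if (denom == 0) return(0)
  n_cg * len / denom
}

#' CpG-ratio in sliding genomic windows
#'
#' One row per window; windows with more than 50% N are dropped. The default
#' 500-bp window matches the 0.5-kb genomic windows used for CpG-density
#' landscapes; `step = window` tiles the genome without overlap.
#'
#' @param genome DNAStringSet or FASTA path
#' @param window window size in bp
#' @param step step between window starts (default `window`)
#' @return data.table(chrom, start, end, n_cpg, n_c, n_g, length_bp, ratio,
#'   gc_percent)
#' @export
sliding_cg_ratio <- function(genome, window = 500L, step = window) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  out <- lapply(names(genome), function(ch) {
    chars <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1L]]
    L <- length(chars)
    if (L < window) return(NULL)
    cumC <- cumsum(chars == "C"); cumG <- cumsum(chars == "G")
    cumN <- cumsum(!(chars %in% c("A", "C", "G", "T")))
    cg <- which(chars[-L] == "C" & chars[-1L] == "G")
    starts <- seq.int(1L, L - window + 1L, by = step)
    ends <- starts + window - 1L
    n_c <- cumC[ends] - cumC[starts] + (chars[starts] == "C")
    n_g <- cumG[ends] - cumG[starts] + (chars[starts] == "G")
    n_n <- cumN[ends] - cumN[starts] + !(chars[starts] %in% c("A", "C", "G", "T"))
    # a CpG lies in the window when both bases do
    n_cpg <- findInterval(ends - 1L, cg) - findInterval(starts - 1L, cg)
    len <- window - n_n
    dt <- data.table::data.table(chrom = ch, start = starts, end = ends,
                                 n_cpg = n_cpg, n_c = n_c, n_g = n_g,
                                 length_bp = len)
    dt[, ratio := ifelse(n_c * n_g == 0, 0, n_cpg * length_bp / (n_c * n_g))]
    dt[, gc_percent := ifelse(length_bp == 0, NA_real_,
                              100 * (n_c + n_g) / length_bp)]
    dt[n_n <= window / 2]
  })
  data.table::rbindlist(out)
}

#' Mean methylation of arbitrary regions from a CpG table
#'
#' Per-region unweighted mean of the per-CpG percents of covered CpGs, the
#' number of covered CpGs, and (when `cpg_sites` is given) the fraction of
#' the region's genomic CpGs that are covered.
#'
#' @param regions data.table(chrom, start, end, ...) or GRanges
#' @param cpg CpG table (depth-filtered)
#' @param cpg_sites optional list from [cpg_sites_from_genome()]
#' @param weighted if TRUE, weight CpGs by coverage instead (off by default:
#'   per-CpG percents are averaged, keeping the statistic depth-independent)
#' @return input regions with mean_meth, n_covered, n_cpg, covered_frac
#' @export
region_mean_methylation <- function(regions, cpg, cpg_sites = NULL,
                                    weighted = FALSE) {
  if (methods::is(regions, "GRanges")) regions <- gr_to_dt(regions)
  regions <- data.table::copy(data.table::as.data.table(regions))
  hit <- GenomicRanges::findOverlaps(dt_to_gr(regions), cpg_gr(cpg))
  qi <- S4Vectors::queryHits(hit); sj <- S4Vectors::subjectHits(hit)
  agg <- data.table::data.table(qi = qi, pct = cpg$percent[sj],
                                nm = cpg$n_meth[sj], nt = cpg$n_total[sj])
  st <- agg[, .(mean_meth = if (weighted) 100 * sum(nm) / sum(nt) else mean(pct),
                n_covered = .N), by = qi]
  regions[, `:=`(mean_meth = NA_real_, n_covered = 0L)]
  regions[st$qi, `:=`(mean_meth = st$mean_meth, n_covered = st$n_covered)]
  if (!is.null(cpg_sites)) {
    if (is.null(regions$n_cpg)) {
      regions[, n_cpg := count_cpgs_in(dt_to_gr(regions), cpg_sites)]
    }
    regions[, covered_frac := ifelse(n_cpg > 0, n_covered / n_cpg, NA_real_)]
  }
  regions[]
}

#' Median methylation of genomic windows by CpG-ratio bin
#'
#' Windows contribute their unweighted mean CpG methylation; windows without
#' a covered CpG are dropped; empty bins yield NA.
#'
#' @param windows output of [sliding_cg_ratio()]
#' @param cpg CpG table
#' @param ratio_bins breakpoints for the CpG-ratio bins
#' @return data.table(bin, ratio_lo, ratio_hi, median_meth, n_windows)
#' @export
methylation_by_cg_ratio <- function(windows, cpg,
                                    ratio_bins = seq(0, 1.2, by = 0.1)) {
  w <- region_mean_methylation(windows, cpg)
  w <- w[n_covered >= 1L]
  brk <- unique(c(ratio_bins, Inf))
  w[, bin := cut(ratio, brk, right = FALSE)]
  res <- w[, .(median_meth = stats::median(mean_meth), n_windows = .N),
           by = bin]
  all_bins <- data.table::data.table(bin = cut(brk[-length(brk)], brk, right = FALSE))
  res <- merge(all_bins, res, by = "bin", all.x = TRUE)
  res[is.na(n_windows), n_windows := 0L]
  res[, `:=`(ratio_lo = brk[as.integer(bin)], ratio_hi = brk[as.integer(bin) + 1L])]
  data.table::setorder(res, ratio_lo)
  res[, .(bin, ratio_lo, ratio_hi, median_meth, n_windows)]
}

#' Global mean CpG methylation
#'
#' Unweighted mean of per-CpG percents over a (depth-filtered) CpG table.
#' @param cpg CpG table
#' @return percent in [0, 100]
#' @export
global_mean_methylation <- function(cpg) {
  if (nrow(cpg) == 0L) stop("empty CpG table")
  mean(cpg$percent)
}

#' Annotate CGIs by genomic feature
#'
#' Priority: promoter (overlaps any transcript TSS) > CDS (overlaps a coding
#' exon but no TSS) > intron (inside a gene but no exon/TSS) > intergenic.
#' Exon intervals stand in for CDS when no dedicated CDS annotation exists.
#'
#' @param cgis GRanges (with cgi_id, n_cpg) or data.table
#' @param ann annotation bundle from [load_annotations()]
#' @return data.table(cgi_id, chrom, start, end, n_cpg, feature_class)
#' @export
annotate_cgi_features <- function(cgis, ann) {
  if (!methods::is(cgis, "GRanges")) cgis <- dt_to_gr(data.table::as.data.table(cgis),
                                                      keep = intersect(c("cgi_id", "n_cpg"), names(cgis)))
  dt <- gr_to_dt(cgis)
  if (is.null(dt$cgi_id)) dt[, cgi_id := sprintf("cgi_%04d", .I)]
  tssg <- GenomicRanges::GRanges(ann$transcripts$chrom,
                                 IRanges::IRanges(ann$transcripts$tss, ann$transcripts$tss))
  exg <- dt_to_gr(ann$exons)
  geng <- genes_gr(ann$genes)
  has_tss <- IRanges::overlapsAny(cgis, tssg)
  has_exon <- IRanges::overlapsAny(cgis, exg)
  has_gene <- IRanges::overlapsAny(cgis, geng)
  dt[, feature_class := ifelse(has_tss, "promoter",
                        ifelse(has_exon, "CDS",
                        ifelse(has_gene, "intron", "intergenic")))]
  dt[]
}

#' Classify CGIs by mean methylation
#'
#' Classes partition [0, 100] at 10 and 50: unmethylated (mean < 10%), low
#' (10-50%), high (> 50%). A CGI whose covered-CpG fraction falls below
#' `min_covered_fraction` (default 35%) is NA.
#'
#' @param cgi_ann output of [annotate_cgi_features()] (needs n_cpg)
#' @param cpg depth-filtered CpG table
#' @param min_covered_fraction minimum fraction of the CGI's CpGs covered
#' @param weighted see [region_mean_methylation()]
#' @return input with mean_meth, covered_frac, meth_class
#' @export
classify_cgi_methylation <- function(cgi_ann, cpg, min_covered_fraction = 0.35,
                                     weighted = FALSE) {
  x <- data.table::as.data.table(cgi_ann)
  stopifnot_cols(x, c("chrom", "start", "end", "n_cpg"), "CGI table")
  if (any(x$n_cpg == 0L)) {
    warning(sprintf("%d CGI(s) contain no CpG in the genome sequence; class NA",
                    sum(x$n_cpg == 0L)))
  }
  x <- region_mean_methylation(x, cpg)
  x[, covered_frac := ifelse(n_cpg > 0, n_covered / n_cpg, NA_real_)]
  x[, meth_class := data.table::fifelse(
        is.na(covered_frac) | covered_frac < min_covered_fraction |
          is.na(mean_meth), NA_character_,
        data.table::fifelse(mean_meth < 10, "unmethylated",
          data.table::fifelse(mean_meth > 50, "high", "low")))]
  x[]
}

#' Proportions of CGI methylation classes
#'
#' @param cgi_classes output of [classify_cgi_methylation()]
#' @return data.table(meth_class, n, percent); percents sum to 100 over
#'   non-NA classes
#' @export
cgi_class_proportions <- function(cgi_classes) {
  x <- cgi_classes[!is.na(meth_class)]
  res <- x[, .(n = .N), by = meth_class]
  res[, percent := 100 * n / sum(n)]
  lev <- data.table::data.table(meth_class = c("unmethylated", "low", "high"))
  res <- merge(lev, res, by = "meth_class", all.x = TRUE, sort = FALSE)
  res[is.na(n), `:=`(n = 0L, percent = 0)]
  res[]
}

#' Define one promoter per gene
#'
#' Promoters span -1000 to +500 bp from each annotated transcript TSS
#' (strand-oriented); when a gene has several TSS, the promoter with the
#' highest CpG ratio is kept. Windows truncated at contig ends are flagged.
#'
#' @param ann annotation bundle (transcripts with tss/strand) including
#'   `chrom_lengths`
#' @param genome DNAStringSet used to compute CpG ratio and GC content
#' @return data.table(gene_id, chrom, strand, start, end, tss, cpg_ratio,
#'   gc_percent, truncated)
#' @export
define_promoters <- function(ann, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  tx <- data.table::copy(ann$transcripts)
  tx[, `:=`(
    start = ifelse(strand == "+", tss - 1000L, tss - 500L),
    end = ifelse(strand == "+", tss + 499L, tss + 999L))]
  lens <- setNames(Biostrings::width(genome), names(genome))
  tx[, truncated := start < 1L | end > lens[chrom]]
  tx[, `:=`(start = pmax(start, 1L), end = pmin(end, lens[chrom]))]
  res <- data.table::rbindlist(lapply(split(tx, tx$chrom), function(d) {
    v <- Biostrings::Views(genome[[d$chrom[1L]]], start = d$start, end = d$end)
    f <- Biostrings::letterFrequency(v, c("C", "G", "N"))
    len <- (d$end - d$start + 1L) - f[, "N"]
    ncg <- Biostrings::vcountPattern("CG", v)
    d[, cpg_ratio_val := ifelse(f[, "C"] * f[, "G"] == 0, 0,
                                ncg * len / (f[, "C"] * f[, "G"]))]
    d[, gc_percent := ifelse(len == 0, NA_real_, 100 * (f[, "C"] + f[, "G"]) / len)]
    d
  }))
  # one promoter per gene: the highest CpG ratio among its TSS
  data.table::setorder(res, gene_id, -cpg_ratio_val)
  res <- res[, .SD[1L], by = gene_id]
  data.table::setorder(res, chrom, start)
  res[, .(gene_id, chrom, strand, start, end, tss,
          cpg_ratio = cpg_ratio_val, gc_percent, truncated)]
}

#' Classify promoters into LCP / ICP / HCP
#'
#' HCP: CpG ratio above the upper cutoff and GC content above `gc_min`;
#' LCP: CpG ratio below the lower cutoff; ICP otherwise. Cutoffs are
#' species-specific inputs (see [suggest_promoter_cutoffs()]).
#'
#' @param promoters output of [define_promoters()]
#' @param lower,upper CpG-ratio cutoffs (lower < upper)
#' @param gc_min GC-content gate for HCP, percent
#' @return input with a `class` column in {LCP, ICP, HCP}
#' @export
classify_promoters <- function(promoters, lower, upper, gc_min = 55) {
  if (lower >= upper) stop("lower cutoff must be below upper cutoff")
  x <- data.table::copy(data.table::as.data.table(promoters))
  x[, class := data.table::fifelse(
        cpg_ratio > upper & gc_percent > gc_min, "HCP",
        data.table::fifelse(cpg_ratio < lower, "LCP", "ICP"))]
  x[]
}

#' Suggest LCP/ICP/HCP CpG-ratio cutoffs from the promoter-ratio density
#'
#' Finds antimodes of the kernel density of promoter CpG ratios; with two or
#' more antimodes the first and last are proposed as (lower, upper), with
#' one antimode a +/-0.05 band around it. This is a starting point only and
#' is never applied silently.
#'
#' @param ratios numeric vector of promoter CpG ratios
#' @return list(lower, upper)
#' @export
suggest_promoter_cutoffs <- function(ratios) {
  d <- stats::density(ratios, na.rm = TRUE)
  sg <- diff(sign(diff(d$y)))
  antimodes <- d$x[which(sg == 2) + 1L]
  if (length(antimodes) >= 2L) {
    list(lower = antimodes[1L], upper = antimodes[length(antimodes)])
  } else if (length(antimodes) == 1L) {
    list(lower = antimodes - 0.05, upper = antimodes + 0.05)
  } else {
    q <- stats::quantile(ratios, c(1 / 3, 2 / 3), na.rm = TRUE)
    list(lower = unname(q[1L]), upper = unname(q[2L]))
  }
}

#' Average methylation profile over genes (metaplot)
#'
#' Twenty equal-sized windows over each autosomal gene body plus ten 1-kb
#' flanking windows on each side, strand-oriented (bin 1 is the most distal
#' upstream bin). A gene contributes a bin only when the bin has a covered
#' CpG; genes shorter than `n_body_bins` bp are skipped and counted.
#'
#' @param genes gene table (isoform-merged)
#' @param cpg CpG table
#' @param n_body_bins number of gene-body bins
#' @param flank_bins number of flanking bins on each side
#' @param flank_bin_bp width of each flanking bin
#' @param chrx chromosome excluded from the profile (NULL keeps all)
#' @return data.table(bin, zone, mean_meth, n_genes); attribute
#'   `n_skipped` counts too-short genes
#' @export
gene_metaplot <- function(genes, cpg, n_body_bins = 20L, flank_bins = 10L,
                          flank_bin_bp = 1000L, chrx = "chrX") {
  g <- data.table::as.data.table(genes)
  if (!is.null(chrx)) g <- g[chrom != chrx]
  short <- g[, end - start + 1L] < n_body_bins
  n_skipped <- sum(short)
  g <- g[!short]
  total_bins <- n_body_bins + 2L * flank_bins
  per_gene <- lapply(seq_len(nrow(g)), function(i) {
    s <- g$start[i]; e <- g$end[i]; plus <- g$strand[i] == "+"
    body_brk <- s + round((e - s + 1L) * seq(0L, n_body_bins) / n_body_bins)
    up <- s - flank_bin_bp * (flank_bins:0)
    dn <- e + 1L + flank_bin_bp * (0:flank_bins)
    brk <- c(up[-length(up)], body_brk, dn[-1L])
    # brk has total_bins + 1 boundaries; bin j = [brk[j], brk[j+1]-1]
    cc <- cpg[chrom == g$chrom[i] & pos >= brk[1L] & pos < brk[length(brk)]]
    if (nrow(cc) == 0L) return(NULL)
    bin <- findInterval(cc$pos, brk)
    m <- cc[, .(mm = mean(percent)), by = .(bin = bin)]
    if (!plus) m[, bin := total_bins + 1L - bin]
    m
  })
  prof <- data.table::rbindlist(per_gene)
  res <- prof[, .(mean_meth = mean(mm), n_genes = .N), by = bin]
  base <- data.table::data.table(bin = seq_len(total_bins))
  res <- merge(base, res, by = "bin", all.x = TRUE)
  res[is.na(n_genes), n_genes := 0L]
  res[, zone := data.table::fifelse(bin <= flank_bins, "upstream",
        data.table::fifelse(bin <= flank_bins + n_body_bins, "body", "downstream"))]
  data.table::setattr(res, "n_skipped", n_skipped)
  res[, .(bin, zone, mean_meth, n_genes)]
}

#' Per-gene body methylation
#'
#' Unweighted mean of covered-CpG percents from +500 bp after the TSS to the
#' end of the (isoform-merged) gene annotation, strand-oriented; NA when the
#' region holds no covered CpG.
#'
#' @param genes gene table
#' @param cpg CpG table
#' @return data.table(gene_id, chrom, mean_meth, n_covered)
#' @export
gene_body_methylation <- function(genes, cpg) {
  g <- data.table::as.data.table(genes)
  reg <- g[, .(gene_id, chrom,
               start = ifelse(strand == "+", start + 500L, start),
               end = ifelse(strand == "+", end, end - 500L))]
  reg <- reg[end >= start]
  out <- region_mean_methylation(reg, cpg)
  empty <- g[!gene_id %in% out$gene_id,
             .(gene_id, chrom, start = NA_integer_, end = NA_integer_,
               mean_meth = NA_real_, n_covered = 0L)]
  rbind(out, empty, fill = TRUE)[, .(gene_id, chrom, mean_meth, n_covered)]
}

#' Per-CpG methylation stratified by genomic feature
#'
#' Assigns each covered CpG to one feature with priority promoter
#' ([-1000, +500) around the gene TSS) > exon > intron > intergenic; CpGs in
#' repeats additionally appear in an independent TE layer.
#'
#' @param cpg CpG table
#' @param ann annotation bundle
#' @return data.table(feature, chrom, pos, percent) in long form
#' @export
feature_stratified_methylation <- function(cpg, ann) {
  cg <- cpg_gr(cpg)
  g <- ann$genes
  prom <- g[, .(chrom,
                start = ifelse(strand == "+", tss - 1000L, tss - 500L),
                end = ifelse(strand == "+", tss + 499L, tss + 999L))]
  in_prom <- IRanges::overlapsAny(cg, dt_to_gr(prom))
  in_exon <- IRanges::overlapsAny(cg, dt_to_gr(ann$exons))
  in_gene <- IRanges::overlapsAny(cg, genes_gr(g))
  feature <- ifelse(in_prom, "promoter",
             ifelse(in_exon, "exon",
             ifelse(in_gene, "intron", "intergenic")))
  out <- data.table::data.table(feature = feature, chrom = cpg$chrom,
                                pos = cpg$pos, percent = cpg$percent)
  if (length(ann$repeats)) {
    in_te <- IRanges::overlapsAny(cg, ann$repeats)
    te <- data.table::data.table(feature = "TE", chrom = cpg$chrom[in_te],
                                 pos = cpg$pos[in_te],
                                 percent = cpg$percent[in_te])
    out <- rbind(out, te)
  }
  out[]
}
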