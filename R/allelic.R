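# Read-level prediction of allelic (imprinted) DMRs. The discriminator
# between allelic and random partial methylation is the single-read
# methylation score: candidate regions contain a mixture of fully
# methylated and fully unmethylated reads at ~50% aggregate methylation.

#' Scan the genome in sliding windows of read-level statistics
#'
#' Windows of `window` bp sliding by `step` bp on a fixed grid (starts 1,
#' 1+step, ...). A read overlaps a window when at least one of its CpG
#' calls lies in the window; its fully-methylated/unmethylated status is
#' judged over ALL of the read's calls (reads are pre-filtered to >= 3
#' CpGs). Window mean methylation is the unweighted mean over the CpG
#' table's CpGs inside the window (`meth_source = "reads"` switches to the
#' mean over in-window read calls). Only windows overlapped by at least one
#' read call are emitted; windows with fewer than `min_reads` reads carry
#' `low_reads = TRUE`.
#'
#' @param calls read-call table from [read_readlevel_calls()] /
#'   [normalize_read_calls()]
#' @param cpg CpG table (aggregate methylation source)
#' @param window window size in bp (default 50)
#' @param step step in bp (default 10; must divide into the scan grid)
#' @param min_reads minimum reads per window before flagging (default 5)
#' @param meth_source "cpg_table" (default) or "reads"
#' @return data.table(chrom, start, end, n_reads, n_fully_m, n_fully_u,
#'   pct_fully_m, pct_fully_u, pct_full, delta, mean_meth, n_cpg, low_reads)
#' @export
window_scan <- function(calls, cpg, window = 50L, step = 10L, min_reads = 5L,
                        meth_source = c("cpg_table", "reads")) {
  meth_source <- match.arg(meth_source)
  stopifnot(window >= step)
  calls <- data.table::as.data.table(calls)
  reads <- calls[, .(fully_m = all(state == "M"), fully_u = all(state == "U")),
                 by = .(chrom, read_id)]
  # window-grid indices k (start = k*step + 1) containing a position p
  k_range <- function(p) {
    lo <- ceiling((p - window) / step)
    hi <- (p - 1L) %/% step
    list(lo = pmax(as.integer(lo), 0L), hi = as.integer(hi))
  }
  expand_to_windows <- function(dt) {
    kr <- k_range(dt$pos)
    reps <- kr$hi - kr$lo + 1L
    out <- dt[rep(seq_len(.N), reps)]
    ks <- rep(kr$lo, reps) + (sequence(reps) - 1L)
    out[, win_start := as.integer(ks) * step + 1L]
    out
  }
  wc <- expand_to_windows(calls[, .(chrom, pos, read_id)])
  wc <- unique(wc[, .(chrom, win_start, read_id)])
  wc <- merge(wc, reads, by = c("chrom", "read_id"))
  stat <- wc[, .(n_reads = .N, n_fm = sum(fully_m), n_fu = sum(fully_u)),
             by = .(chrom, win_start)]

  mcol <- if (meth_source == "cpg_table") {
    mc <- expand_to_windows(cpg[, .(chrom, pos, percent)])
    mc[, .(mean_meth = mean(percent), n_cpg = .N), by = .(chrom, win_start)]
  } else {
    rc <- expand_to_windows(calls[, .(chrom, pos, state)])
    rc[, .(mean_meth = 100 * mean(state == "M"),
           n_cpg = data.table::uniqueN(pos)), by = .(chrom, win_start)]
  }
  stat <- merge(stat, mcol, by = c("chrom", "win_start"), all.x = TRUE)
  stat[is.na(n_cpg), n_cpg := 0L]
  stat[, `:=`(start = win_start, end = win_start + window - 1L,
              pct_fully_m = 100 * n_fm / n_reads,
              pct_fully_u = 100 * n_fu / n_reads)]
  stat[, `:=`(pct_full = pct_fully_m + pct_fully_u,
              delta = abs(pct_fully_m - pct_fully_u),
              low_reads = n_reads < min_reads)]
  data.table::setorder(stat, chrom, start)
  stat[, .(chrom, start, end, n_reads, n_fully_m = n_fm, n_fully_u = n_fu,
           pct_fully_m, pct_fully_u, pct_full, delta, mean_meth, n_cpg,
           low_reads)]
}

#' Filter windows on the allelic-methylation gates
#'
#' A window passes when its mean methylation lies between 30 and 60%
#' (inclusive), more than 90% of its overlapping reads are either fully
#' methylated or fully unmethylated, the difference between the percentages
#' of fully methylated and fully unmethylated reads is below 40, and it has
#' at least `min_reads` reads.
#'
#' @param stats output of [window_scan()]
#' @param mean_range inclusive mean-methylation range, percent
#' @param min_pct_full strict lower bound on percent of fully called reads
#' @param max_delta strict upper bound on the fully-M vs fully-U difference
#' @param min_reads minimum reads per window
#' @return the passing subset of `stats`
#' @export
filter_windows <- function(stats, mean_range = c(30, 60), min_pct_full = 90,
                           max_delta = 40, min_reads = 5L) {
  stats[!is.na(mean_meth) &
          mean_meth >= mean_range[1] & mean_meth <= mean_range[2] &
          pct_full > min_pct_full &
          delta < max_delta &
          n_reads >= min_reads]
}

#' Merge consecutive passing windows into candidate regions
#'
#' Windows are unioned when they overlap or touch (book-ended), the
#' interval-merge semantics of bedtools, plus windows whose starts differ
#' by exactly `step` (adjacent in the scan). Each merged region carries the
#' number of distinct covered CpGs in its span and the unweighted mean
#' methylation over them.
#'
#' @param passing output of [filter_windows()]
#' @param cpg CpG table used for n_cpg and mean methylation
#' @param step scan step in bp
#' @return data.table(chrom, start, end, size_bp, n_windows, n_cpg,
#'   mean_meth)
#' @export
merge_windows <- function(passing, cpg, step = 10L) {
  if (nrow(passing) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), size_bp = integer(),
                                  n_windows = integer(), n_cpg = integer(),
                                  mean_meth = numeric()))
  }
  p <- data.table::copy(passing)
  data.table::setorder(p, chrom, start)
  p[, grp := {
    new_grp <- c(TRUE, start[-1L] > cummax(end[-.N]) + 1L &
                         diff(start) != step)
    cumsum(new_grp)
  }, by = chrom]
  merged <- p[, .(start = min(start), end = max(end), n_windows = .N),
              by = .(chrom, grp)][, grp := NULL]
  merged[, size_bp := end - start + 1L]
  mm <- region_mean_methylation(merged, cpg)
  merged[, `:=`(n_cpg = mm$n_covered, mean_meth = mm$mean_meth)]
  data.table::setorder(merged, chrom, start)
  merged[, .(chrom, start, end, size_bp, n_windows, n_cpg, mean_meth)]
}

#' Apply prediction-mode filters to merged candidates
#'
#' Regions on the X chromosome and regions overlapping the exclusion
#' annotation (developmental genes with variable allele-specific
#' methylation, e.g. HOX/TBX families) are removed first; then the mode
#' gates: stringent keeps regions larger than 350 bp with at least 20 CpGs,
#' lenient keeps regions with at least 10 CpGs and no size threshold.
#'
#' @param candidates output of [merge_windows()]
#' @param mode "stringent" or "lenient"
#' @param exclusions GRanges (or NULL) of excluded regions
#' @param chrx_name name of the X chromosome; must be one of `chrom_names`
#' @param chrom_names all chromosome names of the assembly
#' @param min_cpg,min_size_bp override the mode defaults if non-NULL
#' @return filtered candidate table with a `mode` column
#' @export
apply_mode_filters <- function(candidates, mode = c("stringent", "lenient"),
                               exclusions = NULL, chrx_name = "chrX",
                               chrom_names = NULL, min_cpg = NULL,
                               min_size_bp = NULL) {
  mode <- match.arg(mode)
  if (!is.null(chrom_names) && !(chrx_name %in% chrom_names)) {
    stop(sprintf("unknown X chromosome name '%s'", chrx_name))
  }
  x <- candidates[chrom != chrx_name]
  if (!is.null(exclusions) && length(exclusions) && nrow(x)) {
    x <- x[!IRanges::overlapsAny(dt_to_gr(x), exclusions)]
  }
  if (mode == "stringent") {
    min_cpg <- min_cpg %||% 20L
    min_size_bp <- min_size_bp %||% 350L
    x <- x[n_cpg >= min_cpg & size_bp > min_size_bp]
  } else {
    min_cpg <- min_cpg %||% 10L
    x <- x[n_cpg >= min_cpg]
  }
  x <- data.table::copy(x)
  data.table::set(x, j = "mode", value = mode)
  x[]
}

#' Associate candidate DMRs with their nearest gene
#'
#' Distance to the isoform-merged gene body (0 when overlapping);
#' candidates farther than `max_distance_bp` from any gene stay unassigned.
#'
#' @param dmrs candidate table
#' @param genes gene table
#' @param max_distance_bp maximum assignment distance (default 50 kb)
#' @return input with nearest_gene, ortholog (if present) and distance_bp
#' @export
associate_genes <- function(dmrs, genes, max_distance_bp = 50000L) {
  x <- data.table::copy(data.table::as.data.table(dmrs))
  x[, `:=`(nearest_gene = NA_character_, distance_bp = NA_integer_)]
  if (!is.null(genes$ortholog)) x[, ortholog := NA_character_]
  if (nrow(x) == 0L || nrow(genes) == 0L) return(x[])
  hit <- GenomicRanges::distanceToNearest(dt_to_gr(x), genes_gr(genes))
  qi <- S4Vectors::queryHits(hit)
  gi <- S4Vectors::subjectHits(hit)
  d <- S4Vectors::mcols(hit)$distance
  keep <- d <= max_distance_bp
  x[qi[keep], `:=`(nearest_gene = genes$gene_id[gi[keep]],
                   distance_bp = as.integer(d[keep]))]
  if (!is.null(genes$ortholog)) {
    x[qi[keep], ortholog := genes$ortholog[gi[keep]]]
  }
  x[]
}

#' Aggregate predicted DMR genes across species
#'
#' Genes with a predicted allelic DMR in at least `min_species` species,
#' ranked by the number of species, then by the number of species with a
#' stringent-mode call.
#'
#' @param per_species named list (per species) of gene-associated candidate
#'   tables carrying `nearest_gene`, `ortholog` and `mode`
#' @param ortholog_map data.table(species, gene_id, ortholog); genes absent
#'   from the map are flagged and counted per-species only
#' @param min_species minimum number of species (default 2)
#' @return data.table(ortholog, n_species, n_stringent, species)
#' @export
cross_species_dmr_genes <- function(per_species, ortholog_map,
                                    min_species = 2L) {
  om <- data.table::as.data.table(ortholog_map)
  if (nrow(om) == 0L) {
    warning("empty ortholog map; no cross-species aggregation possible")
    return(data.table::data.table(ortholog = character(),
                                  n_species = integer(),
                                  n_stringent = integer(),
                                  species = character()))
  }
  rows <- data.table::rbindlist(lapply(names(per_species), function(sp) {
    d <- per_species[[sp]]
    d <- d[!is.na(nearest_gene)]
    if (nrow(d) == 0L) return(NULL)
    d <- merge(d[, .(gene_id = nearest_gene, mode)],
               om[species == sp, .(gene_id, ortholog)],
               by = "gene_id", all.x = TRUE)
    if (anyNA(d$ortholog)) {
      warning(sprintf("%d DMR gene(s) in %s absent from the ortholog map",
                      data.table::uniqueN(d[is.na(ortholog), gene_id]), sp))
      d <- d[!is.na(ortholog)]
    }
    d[, .(stringent = any(mode == "stringent")), by = ortholog][, species := sp]
  }))
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.table::data.table(ortholog = character(),
                                  n_species = integer(),
                                  n_stringent = integer(),
                                  species = character()))
  }
  res <- rows[, .(n_species = .N, n_stringent = sum(stringent),
                  species = paste(sort(species), collapse = ",")),
              by = ortholog]
  res <- res[n_species >= min_species]
  data.table::setorder(res, -n_species, -n_stringent, ortholog)
  res[]
}
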