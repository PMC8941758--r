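# Read-level prediction of allelic (imprinted) DMRs: 50/10-bp window scan
# of single-read methylation, the 30-60% / >90%-fully-called / delta<40
# gates, merging, stringent and lenient mode filters, gene association and
# cross-species aggregation, evaluated against the implanted truth.
source("analysis/_common.R")

study <- get_study()
outdir <- dir_create("results", "allelic")
al <- CONFIG$allelic

per_species <- list()
sens <- c()
for (sp in names(study$species)) {
  b <- study$species[[sp]]
  cov <- filter_depth(b$cov, CONFIG$min_depth)
  calls <- normalize_read_calls(b$calls, min_cpgs = al$min_read_cpgs)
  stats <- window_scan(calls, cov, al$window, al$step, al$min_reads)
  passing <- filter_windows(stats, al$mean_meth_range, al$min_pct_full,
                            al$max_delta, al$min_reads)
  merged <- merge_windows(passing, cov, al$step)
  calls_by_mode <- rbindlist(lapply(c("stringent", "lenient"), function(m) {
    cand <- apply_mode_filters(merged, m, b$annotations$exclusions,
                               CONFIG$chrx, names(b$annotations$chrom_lengths))
    associate_genes(cand, b$annotations$genes, al$max_gene_distance_bp)
  }))
  fwrite(calls_by_mode, file.path(outdir, paste0(sp, "_dmrs.tsv")), sep = "\t")
  per_species[[sp]] <- calls_by_mode

  tr <- b$truth$imprinted[stringent_detectable == TRUE]
  hit <- vapply(seq_len(nrow(tr)), function(i)
    calls_by_mode[mode == "stringent" & chrom == tr$chrom[i] &
                    start <= tr$end[i] & end >= tr$start[i], .N] > 0,
    logical(1))
  pm <- b$truth$pmds
  in_pmd <- sum(vapply(seq_len(nrow(pm)), function(i)
    calls_by_mode[chrom == pm$chrom[i] & start <= pm$end[i] &
                    end >= pm$start[i], .N], integer(1)))
  sens <- c(sens, hit)
  cat(sprintf(
    "%s: %s passing windows -> %d merged candidates; %d stringent / %d lenient DMRs; %d/%d truth loci hit in stringent mode; %d calls inside random-partial domains\n",
    sp, format(nrow(passing), big.mark = ","), nrow(merged),
    calls_by_mode[mode == "stringent", .N], calls_by_mode[mode == "lenient", .N],
    sum(hit), length(hit), in_pmd))
}

tab <- cross_species_dmr_genes(per_species, study$ortholog_map,
                               CONFIG$cross_species$dmr_min_species)
fwrite(tab, file.path(outdir, "cross_species_dmr_genes.tsv"), sep = "\t")
cat(sprintf("stringent-mode sensitivity pooled over species: %.3f\n", mean(sens)))
cat(sprintf("%d ortholog genes carry predicted DMRs in >= %d species\n",
            nrow(tab), CONFIG$cross_species$dmr_min_species))
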