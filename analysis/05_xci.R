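# X-inactivation analysis: promoter-CGI methylation on chrX vs autosomes,
# non-CGI 1-kb tile background, escapee prediction (pCGI < 10%) and
# cross-species escapee conservation, evaluated against the implanted truth.
source("analysis/_common.R")

study <- get_study()
outdir <- dir_create("results", "xci")

per_species <- list()
tp <- fp <- fn <- 0L
for (sp in names(study$species)) {
  b <- study$species[[sp]]
  cov <- filter_depth(b$cov, CONFIG$min_depth)
  pcgi <- promoter_cgi_methylation(b$annotations, cov,
                                   CONFIG$landscape$min_covered_frac)
  pt <- x_vs_autosome_pcgi(pcgi, CONFIG$chrx)
  tt <- x_vs_autosome_tiles(cov, b$annotations$cgis,
                            b$annotations$chrom_lengths,
                            CONFIG$xci$tile_bp, CONFIG$chrx)
  esc <- call_escapees(pcgi, CONFIG$chrx, CONFIG$xci$escapee_threshold)
  fwrite(esc, file.path(outdir, paste0(sp, "_escapees.tsv")), sep = "\t")
  per_species[[sp]] <- esc

  called <- esc[is_escapee == TRUE, gene_id]
  truth <- b$truth$escapees$gene_id
  tp <- tp + length(intersect(called, truth))
  fp <- fp + length(setdiff(called, truth))
  fn <- fn + length(setdiff(truth, called))
  cat(sprintf(
    "%s: pCGI median X %.1f%% vs autosome %.1f%% (Wilcoxon p = %.2g); non-CGI tiles X %.1f%% vs %.1f%% (p = %.2g); %d escapees called\n",
    sp, pt$median_x, pt$median_autosome, pt$p_value,
    tt$median_x, tt$median_autosome, tt$p_value, length(called)))
}

shared <- cross_species_escapees(per_species, study$ortholog_map,
                                 CONFIG$cross_species$escapee_min_species)
fwrite(shared, file.path(outdir, "shared_escapees.tsv"), sep = "\t")
cat(sprintf("escapee precision %.2f, recall %.2f; %d escapees shared by >= %d species\n",
            tp / (tp + fp), tp / (tp + fn), nrow(shared),
            CONFIG$cross_species$escapee_min_species))
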