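# Methylome segmentation per species: PMDs (windowed approximation), UMRs
# (meth.cutoff 0.5, nCpG.cutoff 5), DMVs (UMRs >= 5 kb), and cross-species
# conservation of valley genes via 100*n/min(x, y).
source("analysis/_common.R")

study <- get_study()
outdir <- dir_create("results", "segmentation")
sg <- CONFIG$segmentation

dmv_genes <- list()
for (sp in names(study$species)) {
  b <- study$species[[sp]]
  cov <- filter_depth(b$cov, CONFIG$min_depth)
  pmds <- suppressWarnings(detect_pmds(
    cov, win_cpgs = sg$pmd_win_cpgs,
    intermediate_band = sg$pmd_intermediate_band,
    frac_cutoff = sg$pmd_frac_cutoff, merge_gap_bp = sg$pmd_merge_gap_bp,
    min_size_bp = sg$pmd_min_size_bp))
  umrs <- detect_umrs(cov, pmds, sg$meth_cutoff, sg$n_cpg_cutoff, sg$smooth_k)
  dmvs <- call_dmvs(umrs, sg$dmv_min_size_bp)
  for (what in c("pmds", "umrs", "dmvs")) {
    gr <- get(what)
    fwrite(methcompare:::gr_to_dt(gr),
           file.path(outdir, sprintf("%s_%s.tsv", sp, what)), sep = "\t")
  }
  dmv_genes[[sp]] <- dmv_gene_overlap(dmvs, b$annotations$genes)
  recov <- vapply(seq_len(nrow(b$truth$valleys)), function(i) {
    tr <- b$truth$valleys[i]
    d <- methcompare:::gr_to_dt(dmvs)[chrom == tr$chrom & start <= tr$end &
                                        end >= tr$start]
    nrow(d) > 0
  }, logical(1))
  cat(sprintf("%s: %d PMDs, %d UMRs, %d DMVs; %d/%d implanted valleys recovered; DMV genes: %s\n",
              sp, length(pmds), length(umrs), length(dmvs),
              sum(recov), length(recov),
              paste(dmv_genes[[sp]], collapse = ", ")))
}

cons <- conservation_matrix(dmv_genes, study$ortholog_map)
write.table(cons, file.path(outdir, "dmv_conservation.tsv"),
            sep = "\t", quote = FALSE)
cat("pairwise DMV-gene conservation (100*n/min(x,y)):\n")
print(round(cons, 1))
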