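# CpG-density landscape and methylation statistics per species: global CG
# methylation, methylation by CpG-ratio bin, CGI feature/methylation
# classes, promoter classes, gene metaplots.
source("analysis/_common.R")

study <- get_study()
outdir <- dir_create("results", "landscape")

summary_rows <- list()
for (sp in names(study$species)) {
  b <- study$species[[sp]]
  cov <- filter_depth(b$cov, CONFIG$min_depth)
  ann <- b$annotations

  windows <- sliding_cg_ratio(b$genome, window = CONFIG$landscape$ratio_window)
  mbr <- methylation_by_cg_ratio(windows, cov)
  fwrite(mbr, file.path(outdir, paste0(sp, "_meth_by_cg_ratio.tsv")), sep = "\t")

  cgi_cls <- classify_cgi_methylation(annotate_cgi_features(ann$cgis, ann),
                                      cov, CONFIG$landscape$min_covered_frac)
  fwrite(cgi_cls, file.path(outdir, paste0(sp, "_cgi_classes.tsv")), sep = "\t")
  prop <- cgi_class_proportions(cgi_cls)

  promoters <- define_promoters(ann, b$genome)
  prom <- classify_promoters(promoters, CONFIG$landscape$promoter_lower,
                             CONFIG$landscape$promoter_upper,
                             CONFIG$landscape$promoter_gc_min)
  prom <- region_mean_methylation(prom, cov, cpg_sites = ann$cpg_sites)
  fwrite(prom, file.path(outdir, paste0(sp, "_promoters.tsv")), sep = "\t")

  meta <- gene_metaplot(ann$genes, cov, chrx = CONFIG$chrx)
  fwrite(meta, file.path(outdir, paste0(sp, "_gene_metaplot.tsv")), sep = "\t")

  gm <- global_mean_methylation(cov)
  summary_rows[[sp]] <- data.table(
    species = sp, global_mean = gm,
    cgi_unmethylated_pct = prop[meth_class == "unmethylated", percent],
    cgi_low_pct = prop[meth_class == "low", percent],
    cgi_high_pct = prop[meth_class == "high", percent])
  cat(sprintf(
    "%s: global CG methylation %.1f%%; CGI classes %.0f%% unmethylated / %.0f%% low / %.0f%% high; metaplot minimum in bin %d (TSS-proximal)\n",
    sp, gm, prop$percent[1], prop$percent[2], prop$percent[3],
    meta[which.min(mean_meth), bin]))
}
fwrite(rbindlist(summary_rows), file.path(outdir, "summary.tsv"), sep = "\t")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  meta_all <- rbindlist(lapply(names(study$species), function(sp)
    fread(file.path(outdir, paste0(sp, "_gene_metaplot.tsv")))[, species := sp]))
  p <- ggplot(meta_all, aes(bin, mean_meth, colour = species)) +
    geom_line() +
    labs(x = "bin (10 upstream | 20 gene body | 10 downstream)",
         y = "mean CG methylation (%)",
         title = "Gene metaplot, autosomal genes") +
    theme_minimal()
  ggsave(file.path(outdir, "gene_metaplot.pdf"), p, width = 6, height = 4)
}
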