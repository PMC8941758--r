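# End-to-end orchestration: simulate (or load) -> landscape -> segmentation
# -> allelic -> xci -> enrichment -> cross-species report, deterministic
# under a fixed seed.

#' Default pipeline configuration
#'
#' Every threshold is named after its role and set to the workflow's
#' reference value (5X depth filter, 0.5-kb ratio windows, 35% CpG-coverage
#' rule, meth.cutoff 0.5 / nCpG.cutoff 5, 5-kb valleys, 50/10-bp allelic
#' scan with the 30-60% / >90% / <40 gates, stringent >350 bp & >=20 CpGs,
#' lenient >=10 CpGs, escapee pCGI < 10%, DE gates FC > 3 & padj < 0.01).
#'
#' @param seed master seed
#' @param n_species number of simulated species
#' @return nested configuration list
#' @export
default_config <- function(seed = 1L, n_species = 3L) {
  list(
    seed = seed,
    n_species = n_species,
    chrx = "chrX",
    min_depth = 5L,
    genome = list(n_chrom = 3L, chrom_len = c(700000L, 700000L, 600000L),
                  cgi_density = 0.6, gene_density = 4.6),
    methylome = methylome_spec(seed = seed),
    landscape = list(ratio_window = 500L, min_covered_frac = 0.35,
                     promoter_lower = 0.3, promoter_upper = 0.7,
                     promoter_gc_min = 55),
    segmentation = list(meth_cutoff = 0.5, n_cpg_cutoff = 5L,
                        smooth_k = 3L, dmv_min_size_bp = 5000L,
                        pmd_win_cpgs = 101L,
                        pmd_intermediate_band = c(0.3, 0.7),
                        pmd_frac_cutoff = 0.5, pmd_merge_gap_bp = 5000L,
                        pmd_min_size_bp = 10000L),
    allelic = list(window = 50L, step = 10L, min_reads = 5L,
                   min_read_cpgs = 3L, mean_meth_range = c(30, 60),
                   min_pct_full = 90, max_delta = 40,
                   max_gene_distance_bp = 50000L),
    xci = list(escapee_threshold = 10, tile_bp = 1000L),
    enrichment = list(min_fc = 3, max_padj = 0.01),
    cross_species = list(dmr_min_species = 2L, escapee_min_species = 3L),
    stages = c("landscape", "segmentation", "allelic", "xci", "enrichment")
  )
}

#' Run all analysis stages for one species bundle
#'
#' @param bundle a [simulate_species()] bundle (annotations, cov, calls,
#'   de_table, optionally truth)
#' @param config configuration list (see [default_config()])
#' @return named list of per-stage results
#' @export
run_species_stages <- function(bundle, config = default_config()) {
  stages <- config$stages
  if (("allelic" %in% stages) && is.null(config$chrx)) {
    stop("configuration error: chrX name required when the allelic stage is enabled")
  }
  ann <- bundle$annotations
  cov <- filter_depth(bundle$cov, config$min_depth)
  res <- list(species = bundle$species)

  if ("landscape" %in% stages) {
    windows <- sliding_cg_ratio(bundle$genome,
                                window = config$landscape$ratio_window)
    cgi_ann <- annotate_cgi_features(ann$cgis, ann)
    cgi_cls <- classify_cgi_methylation(cgi_ann, cov,
                                        config$landscape$min_covered_frac)
    promoters <- define_promoters(ann, bundle$genome)
    prom_cls <- classify_promoters(promoters,
                                   config$landscape$promoter_lower,
                                   config$landscape$promoter_upper,
                                   config$landscape$promoter_gc_min)
    prom_meth <- region_mean_methylation(
      prom_cls, cov, cpg_sites = ann$cpg_sites)
    prom_meth[!is.na(covered_frac) &
                covered_frac < config$landscape$min_covered_frac,
              mean_meth := NA_real_]
    res$landscape <- list(
      global_mean = global_mean_methylation(cov),
      windows = windows,
      meth_by_ratio = methylation_by_cg_ratio(windows, cov),
      cgi_classes = cgi_cls,
      cgi_proportions = cgi_class_proportions(cgi_cls),
      promoters = prom_meth,
      metaplot = gene_metaplot(ann$genes, cov, chrx = config$chrx),
      gene_body = gene_body_methylation(ann$genes, cov),
      features = feature_stratified_methylation(cov, ann)[
        , .(median_meth = stats::median(percent), n = .N), by = feature])
  }

  if ("segmentation" %in% stages) {
    sg <- config$segmentation
    pmds <- suppressWarnings(detect_pmds(
      cov, win_cpgs = sg$pmd_win_cpgs,
      intermediate_band = sg$pmd_intermediate_band,
      frac_cutoff = sg$pmd_frac_cutoff, merge_gap_bp = sg$pmd_merge_gap_bp,
      min_size_bp = sg$pmd_min_size_bp))
    umrs <- detect_umrs(cov, pmds, meth_cutoff = sg$meth_cutoff,
                        n_cpg_cutoff = sg$n_cpg_cutoff,
                        smooth_k = sg$smooth_k)
    dmvs <- call_dmvs(umrs, sg$dmv_min_size_bp)
    res$segmentation <- list(
      pmds = pmds, umrs = umrs, dmvs = dmvs,
      dmv_genes = dmv_gene_overlap(dmvs, ann$genes),
      genome_fraction = c(
        pmd = sum(GenomicRanges::width(pmds)) / sum(ann$chrom_lengths),
        dmv = sum(GenomicRanges::width(dmvs)) / sum(ann$chrom_lengths)))
  }

  if ("allelic" %in% stages) {
    al <- config$allelic
    calls <- normalize_read_calls(bundle$calls, min_cpgs = al$min_read_cpgs)
    stats <- window_scan(calls, cov, window = al$window, step = al$step,
                         min_reads = al$min_reads)
    passing <- filter_windows(stats, mean_range = al$mean_meth_range,
                              min_pct_full = al$min_pct_full,
                              max_delta = al$max_delta,
                              min_reads = al$min_reads)
    merged <- merge_windows(passing, cov, step = al$step)
    dmrs <- lapply(c(stringent = "stringent", lenient = "lenient"),
                   function(m) {
      cand <- apply_mode_filters(merged, m, exclusions = ann$exclusions,
                                 chrx_name = config$chrx,
                                 chrom_names = names(ann$chrom_lengths))
      associate_genes(cand, ann$genes, al$max_gene_distance_bp)
    })
    res$allelic <- list(merged = merged, stringent = dmrs$stringent,
                        lenient = dmrs$lenient)
  }

  if ("xci" %in% stages) {
    pcgi <- promoter_cgi_methylation(ann, cov,
                                     config$landscape$min_covered_frac)
    res$xci <- list(
      pcgi = pcgi,
      pcgi_test = x_vs_autosome_pcgi(pcgi, config$chrx),
      tile_test = x_vs_autosome_tiles(cov, ann$cgis, ann$chrom_lengths,
                                      config$xci$tile_bp, config$chrx),
      escapees = call_escapees(pcgi, config$chrx,
                               config$xci$escapee_threshold))
  }

  if ("enrichment" %in% stages && !is.null(bundle$de_table)) {
    up <- select_upregulated(bundle$de_table, config$enrichment$min_fc,
                             config$enrichment$max_padj)
    gg <- if (!is.null(bundle$truth)) bundle$truth$germline$gene_id
          else bundle$germline_genes
    bgs <- list(all_genes = ann$genes$gene_id)
    if (!is.null(res$landscape)) {
      mg <- methylated_cgrich_genes(
        res$landscape$promoters[, .(gene_id, class)],
        res$landscape$promoters[, .(gene_id, mean_meth)])
      bgs$methylated_cgrich_promoters <- union(mg, intersect(up, mg))
    }
    res$enrichment <- list(upregulated = up,
                           results = gg_dko_enrichment(gg, up, bgs))
  }
  res
}

#' Aggregate completed species runs across species
#'
#' @param species_results list of [run_species_stages()] outputs (>= 2)
#' @param ortholog_map data.table(species, gene_id, ortholog)
#' @param config configuration list
#' @return list: dmv conservation matrix, cross-species DMR gene table,
#'   cross-species escapee table
#' @export
cross_species_run <- function(species_results, ortholog_map,
                              config = default_config()) {
  if (length(species_results) < 2L) stop("need at least 2 species runs")
  names(species_results) <- vapply(species_results, `[[`, "", "species")
  dmv_genes <- lapply(species_results, function(r) r$segmentation$dmv_genes)
  dmr_calls <- lapply(species_results, function(r) {
    rbind(r$allelic$stringent, r$allelic$lenient)
  })
  esc <- lapply(species_results, function(r) r$xci$escapees)
  list(
    dmv_conservation = conservation_matrix(dmv_genes, ortholog_map),
    dmr_genes = cross_species_dmr_genes(
      dmr_calls, ortholog_map, config$cross_species$dmr_min_species),
    escapees = cross_species_escapees(
      esc, ortholog_map, config$cross_species$escapee_min_species))
}

#' Run the full synthetic pipeline
#'
#' Simulates the configured study, runs every stage for every species,
#' aggregates across species and (optionally) writes a report bundle:
#' per-species BED/TSV outputs, a cross-species conservation table, a JSON
#' summary and the serialized configuration. Deterministic: the same seed
#' yields byte-identical outputs.
#'
#' @param config configuration list from [default_config()]
#' @param outdir output directory, or NULL to skip writing
#' @return list(study, results, cross, summary), invisibly when writing
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  study <- simulate_study(n_species = config$n_species, seed = config$seed,
                          spec = config$methylome,
                          n_chrom = config$genome$n_chrom,
                          chrom_len = config$genome$chrom_len,
                          cgi_density = config$genome$cgi_density,
                          gene_density = config$genome$gene_density)
  # developmental-gene exclusion list: valley genes (the simulated
  # HOX/TBX-like loci with variable allele-specific methylation)
  for (sp in names(study$species)) {
    b <- study$species[[sp]]
    vg <- b$truth$valleys
    study$species[[sp]]$annotations$exclusions <-
      dt_to_gr(b$annotations$genes[gene_id %in% vg$gene_id])
  }
  results <- lapply(study$species, run_species_stages, config = config)
  cross <- if (length(results) >= 2L) {
    cross_species_run(results, study$ortholog_map, config)
  }
  summary <- pipeline_summary(results, cross)
  out <- list(study = study, results = results, cross = cross,
              summary = summary)
  if (!is.null(outdir)) {
    write_report(out, config, outdir)
    return(invisible(out))
  }
  out
}

pipeline_summary <- function(results, cross) {
  per_sp <- lapply(results, function(r) {
    s <- list(species = r$species)
    if (!is.null(r$landscape)) {
      s$global_mean_methylation <- r$landscape$global_mean
      pr <- r$landscape$cgi_proportions
      s$cgi_class_percent <- setNames(as.list(pr$percent), pr$meth_class)
    }
    if (!is.null(r$segmentation)) {
      s$n_dmv <- length(r$segmentation$dmvs)
      s$dmv_genome_fraction <- unname(r$segmentation$genome_fraction["dmv"])
      s$n_pmd <- length(r$segmentation$pmds)
    }
    if (!is.null(r$allelic)) {
      s$n_dmr_stringent <- nrow(r$allelic$stringent)
      s$n_dmr_lenient <- nrow(r$allelic$lenient)
    }
    if (!is.null(r$xci)) {
      s$n_escapees <- sum(r$xci$escapees$is_escapee)
      s$pcgi_x_median <- r$xci$pcgi_test$median_x
      s$pcgi_autosome_median <- r$xci$pcgi_test$median_autosome
    }
    if (!is.null(r$enrichment)) {
      er <- r$enrichment$results
      s$gg_dko_padj <- setNames(as.list(er$padj), er$set_name)
    }
    s
  })
  list(species = per_sp,
       cross_species = if (!is.null(cross)) list(
         dmv_conservation = cross$dmv_conservation,
         n_dmr_genes = nrow(cross$dmr_genes),
         n_shared_escapees = nrow(cross$escapees)))
}

write_report <- function(out, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(rapply(config, unclass, how = "replace"),
                   file.path(outdir, "config.yaml"))
  export_bed <- function(gr, path, names = NULL) {
    if (!length(gr)) return(invisible())
    score <- S4Vectors::mcols(gr)$mean_meth
    S4Vectors::mcols(gr) <- NULL
    if (!is.null(score)) S4Vectors::mcols(gr)$score <- round(score, 2)
    if (!is.null(names)) S4Vectors::mcols(gr)$name <- names
    rtracklayer::export(gr, path)
  }
  for (sp in names(out$results)) {
    r <- out$results[[sp]]
    d <- file.path(outdir, sp)
    dir.create(d, showWarnings = FALSE)
    if (!is.null(r$segmentation)) {
      export_bed(r$segmentation$pmds, file.path(d, "pmds.bed"))
      export_bed(r$segmentation$umrs, file.path(d, "umrs.bed"))
      export_bed(r$segmentation$dmvs, file.path(d, "dmvs.bed"))
      writeLines(sort(r$segmentation$dmv_genes), file.path(d, "dmv_genes.txt"))
    }
    if (!is.null(r$landscape)) {
      data.table::fwrite(r$landscape$cgi_classes, file.path(d, "cgi_classes.tsv"), sep = "\t")
      data.table::fwrite(r$landscape$cgi_proportions, file.path(d, "cgi_proportions.tsv"), sep = "\t")
      data.table::fwrite(r$landscape$promoters, file.path(d, "promoters.tsv"), sep = "\t")
      data.table::fwrite(r$landscape$metaplot, file.path(d, "gene_metaplot.tsv"), sep = "\t")
      data.table::fwrite(r$landscape$meth_by_ratio, file.path(d, "meth_by_cg_ratio.tsv"), sep = "\t")
    }
    if (!is.null(r$allelic)) {
      for (m in c("stringent", "lenient")) {
        dmr <- r$allelic[[m]]
        gr <- if (nrow(dmr)) dt_to_gr(dmr, keep = "mean_meth") else GenomicRanges::GRanges()
        export_bed(gr, file.path(d, sprintf("dmrs_%s.bed", m)),
                   names = if (nrow(dmr)) ifelse(is.na(dmr$nearest_gene), ".", dmr$nearest_gene))
      }
    }
    if (!is.null(r$xci)) {
      data.table::fwrite(r$xci$escapees, file.path(d, "escapees.tsv"), sep = "\t")
    }
    if (!is.null(r$enrichment)) {
      data.table::fwrite(r$enrichment$results, file.path(d, "gg_dko_enrichment.tsv"), sep = "\t")
    }
  }
  if (!is.null(out$cross)) {
    utils::write.table(out$cross$dmv_conservation,
                       file.path(outdir, "dmv_conservation.tsv"),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(out$cross$dmr_genes, file.path(outdir, "dmr_genes.tsv"), sep = "\t")
    data.table::fwrite(out$cross$escapees, file.path(outdir, "shared_escapees.tsv"), sep = "\t")
  }
  jsonlite::write_json(out$summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(outdir)
}
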