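# Generic hypergeometric over-representation with Benjamini-Hochberg
# adjustment, applied to germline ('gg dko') gene sets among methylated
# CpG-rich promoters and among demethylation-upregulated genes.

#' Hypergeometric over-representation test
#'
#' Upper-tail test P(X >= k) with k = |selection ∩ target|, K = |target|,
#' n = |selection|, N = |background|, plus the fold enrichment
#' (k/n) / (K/N). Selection and target must be subsets of the background.
#'
#' @param selection,target,background character vectors of gene ids
#' @param set_name label carried into the result
#' @return one-row data.table(set_name, k, K, n, N, fold, p)
#' @export
hypergeom_enrichment <- function(selection, target, background,
                                 set_name = "set") {
  background <- unique(background)
  selection <- unique(selection); target <- unique(target)
  if (!length(background)) stop("empty background")
  off_t <- setdiff(target, background)
  if (length(off_t)) {
    stop("target gene(s) not in background: ",
         paste(head(off_t, 5L), collapse = ", "))
  }
  off_s <- setdiff(selection, background)
  if (length(off_s)) {
    stop("selection gene(s) not in background: ",
         paste(head(off_s, 5L), collapse = ", "))
  }
  N <- length(background); K <- length(target); n <- length(selection)
  k <- length(intersect(selection, target))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fold <- if (n == 0L || K == 0L) NA_real_ else (k / n) / (K / N)
  data.table::data.table(set_name = set_name, k = k, K = K, n = n, N = N,
                         fold = fold, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; output order matches input.
#' @param pvalues numeric vector in (0, 1]
#' @return adjusted p-values
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Select upregulated genes from a differential-expression table
#'
#' Genes with fold change strictly above `min_fc` and adjusted p strictly
#' below `max_padj` (defaults 3 and 0.01, the demethylation-response gates).
#'
#' @param de_table data.table with gene_id, fold_change, padj
#' @param min_fc,max_padj strict thresholds
#' @return character vector of gene ids
#' @export
select_upregulated <- function(de_table, min_fc = 3, max_padj = 0.01) {
  stopifnot_cols(de_table, c("gene_id", "fold_change", "padj"), "DE table")
  de_table[fold_change > min_fc & padj < max_padj, gene_id]
}

#' Germline ('gg dko') gene-set enrichment
#'
#' Tests over-representation of the germline ortholog set among a selection
#' (typically demethylation-upregulated genes) against one or more
#' backgrounds (all genes; genes with a methylated CpG-rich promoter, i.e.
#' ICP/HCP promoters with mean methylation > 50%), with BH adjustment over
#' the tested backgrounds.
#'
#' @param gg_orthologs germline gene ids in the species namespace
#' @param selection selected gene ids (e.g. [select_upregulated()])
#' @param backgrounds named list of background gene-id vectors
#' @return data.table, one row per background, with padj
#' @export
gg_dko_enrichment <- function(gg_orthologs, selection, backgrounds) {
  res <- data.table::rbindlist(lapply(names(backgrounds), function(bgn) {
    bg <- backgrounds[[bgn]]
    tgt <- intersect(gg_orthologs, bg)
    sel <- intersect(selection, bg)
    if (!length(tgt)) {
      warning(sprintf("no germline gene maps into background '%s'", bgn))
      return(data.table::data.table(set_name = bgn, k = NA_integer_,
                                    K = 0L, n = length(sel),
                                    N = length(unique(bg)),
                                    fold = NA_real_, p = NA_real_))
    }
    hypergeom_enrichment(sel, tgt, bg, set_name = bgn)
  }))
  ok <- !is.na(res$p)
  res[, padj := NA_real_]
  if (any(ok)) res[ok, padj := bh_adjust(res$p[ok])]
  res[]
}

#' Genes with a methylated CpG-rich promoter
#'
#' Operationalized as ICP/HCP promoters with mean methylation above 50%.
#' @param promoter_classes output of [classify_promoters()]
#' @param promoter_meth data.table(gene_id, mean_meth) of promoter
#'   methylation (35% coverage rule applied upstream)
#' @return character vector of gene ids
#' @export
methylated_cgrich_genes <- function(promoter_classes, promoter_meth) {
  x <- merge(promoter_classes[, .(gene_id, class)],
             promoter_meth[, .(gene_id, mean_meth)], by = "gene_id")
  x[class %in% c("ICP", "HCP") & !is.na(mean_meth) & mean_meth > 50, gene_id]
}
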