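# Synthetic methylome generator. Emulates post-alignment WGBS products:
# multi-chromosome genomes with CpG islands and genes, a two-allele
# methylome with unmethylated promoter CGIs, methylated gene bodies and
# repeats, >=5-kb unmethylated valleys over developmental genes, partially
# (per-read randomly) methylated domains, imprinted loci whose reads are a
# mixture of fully methylated and fully unmethylated molecules, an X
# chromosome with ~30%-methylated subject promoter CGIs over a hypomethylated
# non-CGI background, and Poisson/binomial read sampling at configurable
# depth. Ground-truth labels are returned for parameter-recovery tests.

#' Methylome simulation settings
#'
#' Defaults are the package's reference study conditions: fibroblast-like
#' autosomal background (0.80 per allele), hypomethylated X background
#' (0.60), unmethylated promoter CGIs (0.03), valleys at 0.02 spanning >= 5
#' kb, imprinted loci at (0.95, 0.05) so the aggregate sits near 50% with
#' bimodal reads, X subject promoter CGIs at (0.55, 0.05) giving ~30%
#' aggregate, escapee promoter CGIs at 0.02 (imprinted alleles are
#' read-coherent: the allele determines the call and the only within-read
#' noise is the bisulfite-error flip), partially methylated domains
#' drawn per read from U(0.2, 0.8), sequencing depth 12X with 100-bp reads
#' and a per-call flip probability of 0.005 mimicking residual bisulfite
#' non-conversion.
#'
#' @param seed mandatory integer seed
#' @param depth mean per-CpG sequencing depth (lambda)
#' @param read_len read length in bp
#' @param epsilon per-call state flip probability
#' @param n_imprinted,n_valleys,n_germline,n_meth_promoter_bg,n_escapees
#'   number of genes implanted per species in each regime
#' @param p_background_autosome,p_background_x,p_te,p_pcgi,p_valley,
#'   p_methylated_promoter,p_escapee per-allele methylation probabilities
#' @param imprinted,x_subject two-allele probabilities (allele 1, allele 2)
#' @param pmd_level_range per-read methylation level range inside PMDs
#' @return a list of settings (class `methylome_spec`)
#' @export
methylome_spec <- function(seed = 1L, depth = 12, read_len = 100L,
                           epsilon = 0.005,
                           n_imprinted = 10L, n_valleys = 3L,
                           n_germline = 6L, n_meth_promoter_bg = 8L,
                           n_escapees = 3L,
                           p_background_autosome = 0.80,
                           p_background_x = 0.60,
                           p_te = 0.90, p_pcgi = 0.03, p_valley = 0.02,
                           p_methylated_promoter = 0.85, p_escapee = 0.02,
                           imprinted = c(1.0, 0.0),
                           x_subject = c(0.55, 0.05),
                           pmd_level_range = c(0.2, 0.8)) {
  spec <- as.list(environment())
  stopifnot(!is.null(seed), depth > 0,
            all(unlist(spec[grep("^p_", names(spec))]) >= 0),
            all(unlist(spec[grep("^p_", names(spec))]) <= 1),
            all(imprinted >= 0 & imprinted <= 1),
            all(x_subject >= 0 & x_subject <= 1))
  structure(spec, class = "methylome_spec")
}

# evenly spread k picks from a pool (deterministic)
pick_spread <- function(pool, k) {
  if (k <= 0L || !length(pool)) return(integer())
  pool[unique(round(seq(1, length(pool), length.out = min(k, length(pool)))))]
}

rand_seq <- function(n, p) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p)
}

#' Simulate a genome with CpG islands, genes and repeats
#'
#' Sequence is sampled i.i.d. with CG dinucleotides thinned outside CGIs
#' (target observed/expected ratio ~0.4, GC 42%) and CG-rich inside CGIs
#' (o/e ~1, GC 60%). Each gene carries an 800-bp promoter CGI at its TSS;
#' every fifth gene has a second isoform with a shifted TSS; extra CGIs are
#' placed in intergenic, CDS and intron contexts; one 50-kb gene desert per
#' autosome is reserved as a candidate partially methylated domain. The last
#' chromosome is named `chrX`. Deterministic given `seed`.
#'
#' @param n_chrom number of chromosomes (the last one is chrX)
#' @param chrom_len integer vector of lengths (recycled), each >= 50 kb
#' @param cgi_density extra non-promoter CGIs per 100 kb
#' @param gene_density genes per 100 kb
#' @param seed integer seed
#' @param species species label used in gene identifiers
#' @return list: `genome` (DNAStringSet), `annotations` (see
#'   [load_annotations()] for the layout; genes carry an `ortholog` column),
#'   `pmd_candidates` (GRanges), `chrx` (chromosome name)
#' @export
simulate_genome <- function(n_chrom = 3L, chrom_len = c(700000L, 700000L, 600000L),
                            cgi_density = 0.6, gene_density = 4.6,
                            seed = 1L, species = "s1",
                            spec = methylome_spec(seed = seed),
                            pcgi_bp = 800L, imprinted_cgi_bp = 5000L) {
  stopifnot(n_chrom >= 2L)
  # k items split as evenly as possible over g groups
  distribute <- function(k, g) {
    out <- rep(k %/% g, g)
    if (k %% g) out[seq_len(k %% g)] <- out[seq_len(k %% g)] + 1L
    out
  }
  n_autosomes <- n_chrom - 1L
  chrom_len <- as.integer(rep_len(chrom_len, n_chrom))
  if (any(chrom_len < 50000L)) stop("chromosome lengths must be >= 50 kb")
  chroms <- c(paste0("chr", seq_len(n_chrom - 1L)), "chrX")
  set.seed(seed)

  tx_l <- list(); ex_l <- list(); cgi_l <- list(); rep_l <- list()
  pmd_l <- list(); seqs <- character(n_chrom)

  for (ci in seq_len(n_chrom)) {
    chrom <- chroms[ci]; L <- chrom_len[ci]; is_x <- chrom == "chrX"
    desert <- NULL
    usable <- data.table::data.table(a = 10000L, b = L - 15000L)
    if (!is_x) {
      d0 <- as.integer(floor(0.70 * L)) + 1L
      desert <- c(d0, d0 + 49999L)
      usable <- data.table::data.table(a = c(10000L, desert[2] + 10000L),
                                       b = c(d0 - 10000L, L - 15000L))
      pmd_l[[chrom]] <- data.table::data.table(chrom = chrom,
                                               start = desert[1], end = desert[2])
    }
    usable[, len := b - a + 1L]
    n_genes <- max(1L, round(L / 1e5 * gene_density))
    slot <- sum(usable$len) / n_genes
    if (slot < 18000) {
      stop("gene density unattainable at this chromosome length")
    }
    # map an offset along the usable space to a genomic coordinate
    map_coord <- function(u) {
      cum <- cumsum(usable$len)
      k <- findInterval(u, c(0, cum[-length(cum)] + 1), rightmost.closed = FALSE)
      k <- pmin(pmax(k, 1L), nrow(usable))
      off <- u - c(0L, cum)[k]
      as.integer(usable$a[k] + off)
    }
    offs <- as.integer((seq_len(n_genes) - 1L) * slot +
                         runif(n_genes, 0.05, 0.20) * slot)
    g_start <- map_coord(offs)
    body <- as.integer(runif(n_genes, 6000, pmin(14000, slot * 0.6)))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    g_end <- g_start + body - 1L
    tssv <- ifelse(strand == "+", g_start, g_end)

    gid <- sprintf("%s_%s_g%02d", species, chrom, seq_len(n_genes))
    og <- sprintf("og_%s_%02d", chrom, seq_len(n_genes))

    # regime roles, assigned by gene index within the chromosome so that
    # species sharing a layout share ortholog roles (conserved synteny)
    role <- rep("background", n_genes)
    if (is_x) {
      esc <- pick_spread(seq_len(n_genes), spec$n_escapees)
      role[] <- "x_subject"; role[esc] <- "escapee"
    } else {
      pool <- seq_len(n_genes)
      imp <- pick_spread(pool, distribute(spec$n_imprinted, n_autosomes)[ci])
      pool <- setdiff(pool, imp)
      val <- pick_spread(pool, distribute(spec$n_valleys, n_autosomes)[ci])
      pool <- setdiff(pool, val)
      ger <- pick_spread(pool, distribute(spec$n_germline, n_autosomes)[ci])
      pool <- setdiff(pool, ger)
      mbg <- pick_spread(pool, distribute(spec$n_meth_promoter_bg, n_autosomes)[ci])
      role[imp] <- "imprinted"; role[val] <- "valley"
      role[ger] <- "germline"; role[mbg] <- "meth_promoter"
    }

    tx <- data.table::data.table(
      transcript_id = paste0(gid, "_t1"), gene_id = gid, name = og,
      chrom = chrom, strand = strand, start = g_start, end = g_end,
      ortholog = og, role = role)
    # second isoform for every fifth gene: TSS shifted 400 bp into the body
    iso2 <- which(seq_len(n_genes) %% 5L == 0L)
    if (length(iso2)) {
      t2 <- tx[iso2]
      t2[, `:=`(transcript_id = paste0(gene_id, "_t2"),
                start = ifelse(strand == "+", start + 400L, start),
                end = ifelse(strand == "-", end - 400L, end))]
      tx <- rbind(tx, t2)
    }
    tx_l[[chrom]] <- tx
    ex <- tx[, {
      w <- end - start + 1L
      e2s <- start + as.integer(0.45 * w)
      data.table::data.table(
        start = c(start, e2s, end - 399L),
        end = c(start + 299L, e2s + 499L, end))
    }, by = .(gene_id, transcript_id, chrom)]
    ex_l[[chrom]] <- ex

    # promoter CGIs over the gene-level TSS; imprinted loci carry wide
    # CGIs (germline DMRs are kilobase-scale CpG-rich regions)
    up <- ifelse(role == "imprinted", 500L, 200L)
    dn <- ifelse(role == "imprinted", imprinted_cgi_bp - 501L, pcgi_bp - 201L)
    pc <- data.table::data.table(
      chrom = chrom,
      start = ifelse(strand == "+", tssv - up, tssv - dn),
      end = ifelse(strand == "+", tssv + dn, tssv + up),
      cgi_id = sprintf("%s_%s_pcgi%02d", species, chrom, seq_len(n_genes)))
    cgi <- pc
    if (!is_x) {
      n_extra <- round(L / 1e5 * cgi_density)
      kinds <- rep_len(c("intergenic", "intergenic", "cds", "intron"), n_extra)
      gaps <- data.table::data.table(
        m = g_end[-n_genes] + (g_start[-1L] - g_end[-n_genes]) %/% 2L)
      extra <- data.table::rbindlist(lapply(seq_len(n_extra), function(k) {
        if (kinds[k] == "intergenic") {
          m <- gaps$m[1L + (k %% max(1L, nrow(gaps) - 1L))]
          data.table::data.table(chrom = chrom, start = m, end = m + 699L,
                                 cgi_id = sprintf("%s_%s_xcgi%02d", species, chrom, k))
        } else if (kinds[k] == "cds") {
          i <- n_genes - 1L # a background gene late on the chromosome
          e2s <- g_start[i] + as.integer(0.45 * body[i])
          data.table::data.table(chrom = chrom, start = e2s - 100L, end = e2s + 499L,
                                 cgi_id = sprintf("%s_%s_xcgi%02d", species, chrom, k))
        } else {
          i <- n_genes # intron of the last gene
          s <- g_start[i] + as.integer(0.62 * body[i])
          data.table::data.table(chrom = chrom, start = s, end = s + 499L,
                                 cgi_id = sprintf("%s_%s_xcgi%02d", species, chrom, k))
        }
      }))
      cgi <- rbind(cgi, extra)
    }
    cgi_l[[chrom]] <- cgi

    # repeats (TEs) in intergenic gaps
    rp <- data.table::data.table(
      chrom = chrom,
      start = head(g_end, -1) + 3000L)
    rp[, end := start + 599L]
    if (!is_x) rp <- rp[!(start >= desert[1] - 1000L & end <= desert[2] + 1000L)]
    rp_ok <- rp$end < L - 1000L
    rep_l[[chrom]] <- rp[rp_ok]

    # sequence: background with CG thinning, CG-rich islands spliced in
    chars <- rand_seq(L, c(0.29, 0.21, 0.21, 0.29))
    for (r in seq_len(nrow(cgi))) {
      idx <- cgi$start[r]:cgi$end[r]
      chars[idx] <- rand_seq(length(idx), c(0.20, 0.30, 0.30, 0.20))
    }
    in_cgi <- logical(L)
    for (r in seq_len(nrow(cgi))) in_cgi[cgi$start[r]:cgi$end[r]] <- TRUE
    cg_pos <- which(chars[-L] == "C" & chars[-1L] == "G")
    outside <- cg_pos[!in_cgi[cg_pos]]
    kill <- outside[runif(length(outside)) > 0.4]
    chars[kill + 1L] <- sample(c("A", "T"), length(kill), replace = TRUE)
    seqs[ci] <- paste(chars, collapse = "")
  }

  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  tx <- data.table::rbindlist(tx_l)
  ann <- load_annotations(genes = tx[, !c("ortholog", "role")],
                          genome = genome,
                          exons = data.table::rbindlist(ex_l))
  ann$genes <- merge(ann$genes, unique(tx[, .(gene_id, ortholog, role)]),
                     by = "gene_id")
  data.table::setorder(ann$genes, chrom, start)
  cgdt <- data.table::rbindlist(cgi_l)
  ann$cgis <- dt_to_gr(cgdt, keep = "cgi_id")
  S4Vectors::mcols(ann$cgis)$n_cpg <- count_cpgs_in(ann$cgis, ann$cpg_sites)
  ann$repeats <- dt_to_gr(data.table::rbindlist(rep_l))

  list(genome = genome, annotations = ann,
       pmd_candidates = dt_to_gr(data.table::rbindlist(pmd_l)),
       chrx = "chrX")
}

#' Assign a two-allele methylation regime to every CpG
#'
#' Implants the regimes of [methylome_spec()] onto a simulated genome:
#' imprinted loci at promoter CGIs of evenly spaced autosomal genes,
#' >=5-kb valleys over designated developmental genes, per-read random
#' partial methylation over the reserved gene deserts, methylated germline
#' and background promoters, and escapee/subject promoter CGIs on chrX.
#' Role assignment is by gene index within each chromosome, so species
#' simulated with the same layout share ortholog roles (conserved synteny).
#'
#' @param sim output of [simulate_genome()]
#' @param spec a [methylome_spec()]
#' @return list: `methylome` data.table(chrom, pos, p1, p2, regime) covering
#'   every genomic CpG, and `truth` (implanted imprinted loci, valleys,
#'   pmds, escapees, subjects, germline and methylated-promoter gene sets)
#' @export
simulate_methylome <- function(sim, spec = methylome_spec()) {
  ann <- sim$annotations
  genes <- data.table::copy(ann$genes)
  cg <- gr_to_dt(ann$cgis)
  pcgi <- cg[grepl("_pcgi", cgi_id)]
  # promoter CGIs belong to genes in chromosome order
  data.table::setorder(pcgi, chrom, start)

  if (is.null(genes$role)) {
    stop("annotations lack gene regime roles; build them with simulate_genome()")
  }
  data.table::setorder(genes, chrom, start)

  # promoter CGI of each gene = the pCGI whose interval covers its TSS
  pc_gr <- dt_to_gr(pcgi, keep = "cgi_id")
  tss_gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$tss, genes$tss))
  hit <- GenomicRanges::findOverlaps(tss_gr, pc_gr, select = "first")
  genes[, `:=`(pcgi_start = pcgi$start[hit], pcgi_end = pcgi$end[hit])]
  if (anyNA(genes$pcgi_start)) stop("internal: gene without promoter CGI")

  truth_regions <- function(g) {
    data.table::data.table(chrom = g$chrom, start = g$pcgi_start,
                           end = g$pcgi_end, gene_id = g$gene_id,
                           ortholog = g$ortholog)
  }
  imp_t <- truth_regions(genes[role == "imprinted"])
  val_t <- genes[role == "valley",
                 .(chrom, start = start - 500L, end = end + 500L,
                   gene_id, ortholog)]
  pmd_t <- gr_to_dt(sim$pmd_candidates)

  # regime layers must not collide
  ovl <- function(a, b) {
    length(GenomicRanges::findOverlaps(dt_to_gr(a), dt_to_gr(b))) > 0
  }
  if (nrow(imp_t) && nrow(val_t) && ovl(imp_t, val_t)) {
    stop("implanted valley overlaps an imprinted locus")
  }
  if (nrow(pmd_t) && (ovl(pmd_t, imp_t) || ovl(pmd_t, val_t))) {
    stop("implanted PMD overlaps a valley or imprinted locus")
  }

  meth <- data.table::rbindlist(lapply(names(ann$cpg_sites), function(ch) {
    data.table::data.table(chrom = ch, pos = ann$cpg_sites[[ch]])
  }))
  meth[, `:=`(p1 = ifelse(chrom == sim$chrx, spec$p_background_x,
                          spec$p_background_autosome))]
  meth[, p2 := p1]
  meth[, regime := ifelse(chrom == sim$chrx, "background_x", "background")]

  paint <- function(regions, p1v, p2v, label) {
    if (!nrow(regions)) return(invisible())
    hit <- GenomicRanges::findOverlaps(cpg_gr(meth), dt_to_gr(regions))
    i <- unique(S4Vectors::queryHits(hit))
    meth[i, `:=`(p1 = p1v, p2 = p2v, regime = label)]
    invisible()
  }
  paint(gr_to_dt(ann$repeats), spec$p_te, spec$p_te, "te")
  # CGI layers: promoter CGIs unmethylated by default; extra CGIs alternate
  paint(pcgi, spec$p_pcgi, spec$p_pcgi, "pcgi")
  xcgi <- cg[grepl("_xcgi", cgi_id)]
  if (nrow(xcgi)) {
    alt <- seq_len(nrow(xcgi)) %% 2L == 0L
    paint(xcgi[!alt], 0.05, 0.05, "cgi_unmeth")
    paint(xcgi[alt], spec$p_methylated_promoter, spec$p_methylated_promoter,
          "cgi_meth")
  }
  paint(truth_regions(genes[role == "meth_promoter"]),
        spec$p_methylated_promoter, spec$p_methylated_promoter, "meth_promoter")
  paint(truth_regions(genes[role == "germline"]),
        spec$p_methylated_promoter, spec$p_methylated_promoter, "germline")
  paint(truth_regions(genes[role == "x_subject"]),
        spec$x_subject[1], spec$x_subject[2], "x_subject")
  paint(truth_regions(genes[role == "escapee"]),
        spec$p_escapee, spec$p_escapee, "escapee")
  paint(val_t, spec$p_valley, spec$p_valley, "valley")
  paint(imp_t, spec$imprinted[1], spec$imprinted[2], "imprinted")
  paint(pmd_t, NA_real_, NA_real_, "pmd")

  imp_t[, n_cpg := count_cpgs_in(dt_to_gr(imp_t), ann$cpg_sites)]
  imp_t[, stringent_detectable := n_cpg >= 20L & (end - start + 1L) > 350L]

  list(methylome = meth[],
       truth = list(
         imprinted = imp_t[], valleys = val_t[], pmds = pmd_t[],
         escapees = genes[role == "escapee", .(gene_id, ortholog)],
         x_subjects = genes[role == "x_subject", .(gene_id, ortholog)],
         germline = genes[role == "germline", .(gene_id, ortholog)],
         meth_promoter = genes[role == "meth_promoter", .(gene_id, ortholog)],
         roles = genes[, .(gene_id, ortholog, chrom, role)]))
}

#' Simulate bisulfite read-level CpG calls and a coverage table
#'
#' Reads are placed by Poisson sampling (expected per-CpG depth `depth`),
#' each read drawn from one of two alleles with equal probability; every CpG
#' covered by a read from allele a is called methylated with probability
#' p_a, except inside PMDs where the per-read level is uniform on the
#' configured range (random partial methylation). Each call is flipped with
#' probability `epsilon`. The returned coverage table is the exact
#' aggregation of the emitted calls.
#'
#' @param methylome per-CpG (p1, p2, regime) table from [simulate_methylome()]
#' @param chrom_lengths named integer vector
#' @param spec a [methylome_spec()] (depth, read_len, epsilon, pmd range)
#' @param seed integer seed
#' @return list: `calls` (read_id, chrom, pos, state) with every emitted
#'   read, `cov` (aggregated CpG table, unfiltered)
#' @export
simulate_reads <- function(methylome, chrom_lengths, spec = methylome_spec(),
                           seed = spec$seed) {
  set.seed(seed)
  res <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    m <- methylome[chrom == ch]
    n_reads <- stats::rpois(1L, L * spec$depth / spec$read_len)
    if (n_reads == 0L || nrow(m) == 0L) return(NULL)
    rstart <- sample.int(L - spec$read_len + 1L, n_reads, replace = TRUE)
    allele <- sample.int(2L, n_reads, replace = TRUE)
    lev <- runif(n_reads, spec$pmd_level_range[1], spec$pmd_level_range[2])
    rgr <- GenomicRanges::GRanges(ch, IRanges::IRanges(rstart, rstart + spec$read_len - 1L))
    hit <- GenomicRanges::findOverlaps(rgr, cpg_gr(m))
    ri <- S4Vectors::queryHits(hit); cj <- S4Vectors::subjectHits(hit)
    p <- ifelse(m$regime[cj] == "pmd", lev[ri],
                ifelse(allele[ri] == 1L, m$p1[cj], m$p2[cj]))
    call_m <- stats::rbinom(length(p), 1L, p) == 1L
    flip <- stats::runif(length(p)) < spec$epsilon
    call_m <- xor(call_m, flip)
    data.table::data.table(
      read_id = sprintf("%s_r%06d", ch, ri), chrom = ch, pos = m$pos[cj],
      state = ifelse(call_m, "M", "U"))
  })
  calls <- data.table::rbindlist(res)
  data.table::setorder(calls, chrom, read_id, pos)
  cov <- new_cpg_table(calls[, .(n_meth = sum(state == "M"), n_total = .N),
                             by = .(chrom, pos)])
  list(calls = calls[], cov = cov)
}

#' Simulate a differential-expression result table (5-azadC style)
#'
#' Germline genes are implanted as strongly upregulated with tiny adjusted
#' p-values; a small fraction of other genes passes the thresholds as noise;
#' the rest stay near a fold change of 1.
#'
#' @param genes gene table (gene_id)
#' @param germline_ids gene ids implanted as upregulated
#' @param seed integer seed
#' @param frac_noise fraction of non-germline genes passing the DE gates
#' @return data.table(gene_id, fold_change, padj)
#' @export
simulate_de_table <- function(genes, germline_ids, seed = 1L,
                              frac_noise = 0.05) {
  set.seed(seed)
  de <- data.table::data.table(gene_id = genes$gene_id)
  n <- nrow(de)
  de[, `:=`(fold_change = exp(stats::rnorm(n, 0, 0.3)),
            padj = stats::runif(n, 0.02, 1))]
  noise <- sample(which(!(de$gene_id %in% germline_ids)),
                  max(1L, round(frac_noise * n)))
  de[noise, `:=`(fold_change = stats::runif(.N, 3.5, 8),
                 padj = stats::runif(.N, 5e-4, 9e-3))]
  de[gene_id %in% germline_ids,
     `:=`(fold_change = stats::runif(.N, 6, 24),
          padj = 10^stats::runif(.N, -8, -4))]
  de[]
}

#' Simulate one species end to end
#'
#' @param species species label
#' @param seed integer seed (genome, methylome roles, reads and DE table all
#'   derive from it)
#' @param spec a [methylome_spec()]
#' @param ... passed to [simulate_genome()]
#' @return list: genome, annotations, methylome, truth, calls, cov, de_table
#' @export
simulate_species <- function(species, seed, spec = methylome_spec(), ...) {
  sim <- simulate_genome(seed = seed, species = species, spec = spec, ...)
  mt <- simulate_methylome(sim, spec)
  rd <- simulate_reads(mt$methylome, sim$annotations$chrom_lengths, spec,
                       seed = seed + 7L)
  de <- simulate_de_table(sim$annotations$genes, mt$truth$germline$gene_id,
                          seed = seed + 13L)
  # methylated CpG-rich promoters (germline + methylated background genes)
  # are CpG-rich in sequence but, as in real CGI annotation tracks, not
  # annotated as CpG islands
  hidden <- mt$truth$roles[role %in% c("germline", "meth_promoter"), gene_id]
  if (length(hidden)) {
    g <- sim$annotations$genes[gene_id %in% hidden]
    tssg <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$tss, g$tss))
    keep <- !IRanges::overlapsAny(sim$annotations$cgis, tssg)
    sim$annotations$cgis <- sim$annotations$cgis[keep]
  }
  list(species = species, genome = sim$genome, annotations = sim$annotations,
       chrx = sim$chrx, methylome = mt$methylome, truth = mt$truth,
       calls = rd$calls, cov = rd$cov, de_table = de)
}

#' Simulate the default multi-species study
#'
#' Three species with identical layouts (conserved gene order, shared
#' ortholog roles) but independent sequences, methylomes and reads.
#'
#' @param n_species number of species
#' @param seed integer master seed; species s uses seed + 101 * s
#' @param spec a [methylome_spec()]
#' @param ... passed to [simulate_genome()]
#' @return list: `species` (list of [simulate_species()] bundles),
#'   `ortholog_map` data.table(species, gene_id, ortholog)
#' @export
simulate_study <- function(n_species = 3L, seed = 1L,
                           spec = methylome_spec(seed = seed), ...) {
  sp <- lapply(seq_len(n_species), function(s) {
    simulate_species(sprintf("s%d", s), seed = seed + 101L * s, spec = spec, ...)
  })
  names(sp) <- vapply(sp, `[[`, "", "species")
  omap <- data.table::rbindlist(lapply(sp, function(b) {
    data.table::data.table(species = b$species,
                           gene_id = b$annotations$genes$gene_id,
                           ortholog = b$annotations$genes$ortholog)
  }))
  list(species = sp, ortholog_map = omap)
}

#' Write a simulated species bundle to disk
#'
#' Emits FASTA, GTF, CGI/repeat/PMD-candidate BEDs, the coverage table, the
#' read-level call table and truth TSVs under `dir`.
#' @param bundle output of [simulate_species()]
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  ann <- bundle$annotations
  tx <- ann$transcripts
  txgr <- dt_to_gr(tx[, .(chrom, start, end, gene_id, transcript_id)],
                   keep = c("gene_id", "transcript_id"))
  GenomicRanges::strand(txgr) <- tx$strand
  S4Vectors::mcols(txgr)$type <- "transcript"
  ex <- merge(ann$exons, tx[, .(transcript_id, strand)], by = "transcript_id")
  exgr <- dt_to_gr(ex[, .(chrom, start, end, gene_id, transcript_id)],
                   keep = c("gene_id", "transcript_id"))
  GenomicRanges::strand(exgr) <- ex$strand
  S4Vectors::mcols(exgr)$type <- "exon"
  gtf <- c(txgr, exgr)
  S4Vectors::mcols(gtf)$source <- "methcompare_sim"
  rtracklayer::export(sort(gtf), file.path(dir, "genes.gtf"), format = "gtf")
  rtracklayer::export(ann$cgis, file.path(dir, "cgis.bed"))
  if (length(ann$repeats)) {
    rtracklayer::export(ann$repeats, file.path(dir, "repeats.bed"))
  }
  write_cov_table(bundle$cov, file.path(dir, "methylation.cov"))
  write_read_calls(bundle$calls, file.path(dir, "cpg_calls.txt"))
  for (nm in c("imprinted", "valleys", "pmds", "escapees", "germline")) {
    data.table::fwrite(bundle$truth[[nm]],
                       file.path(dir, sprintf("truth_%s.tsv", nm)), sep = "\t")
  }
  data.table::fwrite(bundle$de_table, file.path(dir, "de_table.tsv"), sep = "\t")
  invisible(dir)
}
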