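# Readers/writers for the on-disk formats the workflow touches: Bismark-style
# per-CpG coverage tables, read-level CpG-call tables, FASTA genomes,
# GTF/BED annotations. Internal convention: 1-based closed coordinates,
# per-CpG positions anchored at the C of the plus-strand CpG.

#' Positions of plus-strand CpG cytosines in a genome
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file
#' @return named list (one integer vector per chromosome) of 1-based
#'   positions of the C of each CG dinucleotide
#' @export
cpg_sites_from_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  out <- lapply(seq_along(genome), function(i) {
    GenomicRanges::start(Biostrings::matchPattern("CG", genome[[i]]))
  })
  names(out) <- names(genome)
  out
}

new_cpg_table <- function(dt) {
  stopifnot_cols(dt, c("chrom", "pos", "n_meth", "n_total"), "CpG table")
  dt <- data.table::as.data.table(dt)
  dt[, percent := 100 * n_meth / n_total]
  data.table::setorder(dt, chrom, pos)
  stopifnot(all(dt$n_total >= dt$n_meth), all(dt$n_meth >= 0))
  dt[]
}

#' Combine CpG methylation calls from both strands
#'
#' Assigns a record at position p+1 (the G-strand cytosine) to the
#' plus-strand C at position p and sums the counts. When `cpg_sites` (from
#' [cpg_sites_from_genome()]) is supplied the assignment is exact; otherwise
#' a greedy adjacency rule is used: within each run of consecutive
#' positions, every second record is folded into its left neighbour.
#' Duplicate records for one CpG are summed, not averaged.
#'
#' @param cov data.table with chrom, pos, n_meth, n_total
#' @param cpg_sites optional named list of plus-strand C positions
#' @return strand-combined CpG table (one record per CpG)
#' @export
combine_strands <- function(cov, cpg_sites = NULL) {
  cov <- data.table::as.data.table(cov)
  data.table::setorder(cov, chrom, pos)
  if (!is.null(cpg_sites)) {
    cov[, pos := {
      sites <- cpg_sites[[chrom[1L]]]
      if (is.null(sites)) pos
      else ifelse(!(pos %in% sites) & (pos - 1L) %in% sites, pos - 1L, pos)
    }, by = chrom]
  } else {
    cov[, pos := {
      run <- cumsum(c(TRUE, diff(pos) != 1L))
      off <- seq_len(.N) - match(run, run) # 0-based offset within run
      pos - (off %% 2L)
    }, by = chrom]
  }
  out <- cov[, .(n_meth = sum(n_meth), n_total = sum(n_total)),
             by = .(chrom, pos)]
  new_cpg_table(out)
}

#' Filter a CpG table by sequencing depth
#'
#' @param cpg CpG table
#' @param min_depth minimum total calls per CpG (default 5, the WGBS filter;
#'   use 10 for RRBS-style filtering)
#' @return filtered CpG table
#' @export
filter_depth <- function(cpg, min_depth = 5L) {
  new_cpg_table(cpg[n_total >= min_depth])
}

#' Read a per-CpG methylation coverage table
#'
#' Reads the Bismark `.cov` dialect (chrom, start, end, percent methylation,
#' count methylated, count unmethylated; 1-based inclusive positions on
#' disk), combines strands and applies a depth filter. Lines starting with
#' `#` are ignored. When the stored percent disagrees with the counts by
#' more than 0.5 a warning is raised and the counts win.
#'
#' @param path file path
#' @param min_depth minimum total calls per CpG after strand combination
#' @param collapse combine plus/minus strand records into one record per CpG
#' @param cpg_sites optional list from [cpg_sites_from_genome()] for exact
#'   strand assignment
#' @return CpG table: data.table(chrom, pos, n_meth, n_total, percent)
#' @export
read_cov_table <- function(path, min_depth = 5L, collapse = TRUE,
                           cpg_sites = NULL) {
  head_lines <- readLines(path, n = 100L)
  n_skip <- match(FALSE, startsWith(head_lines, "#"), nomatch = 1L) - 1L
  raw <- data.table::fread(path, header = FALSE, sep = "\t", skip = n_skip,
                           colClasses = "character", fill = TRUE)
  if (ncol(raw) < 6L) stop("coverage table needs 6 tab-separated columns")
  comment <- startsWith(raw$V1, "#")
  line_no <- which(!comment) + n_skip
  raw <- raw[!comment]
  num <- raw[, lapply(.SD, function(x) suppressWarnings(as.numeric(x))),
             .SDcols = 2:6]
  bad <- which(!stats::complete.cases(num) | is.na(raw$V1) | raw$V1 == "")
  if (length(bad)) {
    stop(sprintf("malformed coverage record at line %d of %s",
                 line_no[bad[1L]], path))
  }
  cov <- data.table::data.table(
    chrom = raw$V1, pos = as.integer(num$V2),
    n_meth = as.integer(num$V5), n_total = as.integer(num$V5) + as.integer(num$V6),
    stored_pct = num$V4
  )
  ok <- cov$n_total > 0
  disag <- abs(cov$stored_pct[ok] - 100 * cov$n_meth[ok] / cov$n_total[ok]) > 0.5
  if (any(disag)) {
    warning(sprintf("%d record(s) with percent inconsistent with counts; counts win",
                    sum(disag)))
  }
  cov[, stored_pct := NULL]
  cov <- if (collapse) combine_strands(cov, cpg_sites) else new_cpg_table(cov)
  filter_depth(cov, min_depth)
}

#' Write a CpG table in coverage format
#'
#' Emits the 6-column coverage dialect with a leading comment naming the
#' coordinate convention (1-based inclusive, plus-strand C positions).
#' @param cpg CpG table
#' @param path output path
#' @export
write_cov_table <- function(cpg, path) {
  writeLines("# methcompare coverage table: chrom, pos, pos, percent_methylation, count_methylated, count_unmethylated; 1-based inclusive, plus-strand CpG C positions",
             path)
  out <- cpg[, .(chrom, pos, end = pos, percent = 100 * n_meth / n_total,
                 n_meth, n_unmeth = n_total - n_meth)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read read-level CpG methylation calls
#'
#' Reads the Bismark CpG-context dialect: read id, methylation-state flag
#' (`+` methylated, `-` unmethylated), chrom, 1-based position, call symbol
#' (`Z`/`z`, `M`/`U` also accepted). Calls are grouped per read, optionally
#' collapsed to the plus-strand C, and reads covering fewer than `min_cpgs`
#' CpGs are removed (the pipeline default keeps reads with at least 3 CpGs).
#' Reads whose calls span more than one chromosome are split per chromosome
#' with a warning.
#'
#' @param path file path
#' @param min_cpgs minimum CpG calls per read (default 3)
#' @param collapse collapse minus-strand call positions to the plus-strand C
#'   (requires `cpg_sites`; without sites positions are kept as-is)
#' @param cpg_sites optional list from [cpg_sites_from_genome()]
#' @return read-call table: data.table(read_id, chrom, pos, state) with
#'   state in {"M","U"}, positions strictly increasing within a read
#' @export
read_readlevel_calls <- function(path, min_cpgs = 3L, collapse = TRUE,
                                 cpg_sites = NULL) {
  head_lines <- readLines(path, n = 100L)
  n_skip <- match(FALSE, startsWith(head_lines, "#"), nomatch = 1L) - 1L
  raw <- data.table::fread(path, header = FALSE, sep = "\t", skip = n_skip,
                           colClasses = "character")
  raw <- raw[!startsWith(V1, "#")]
  if (ncol(raw) < 5L) stop("read-level call table needs 5 tab-separated columns")
  calls <- data.table::data.table(
    read_id = raw$V1, chrom = raw$V3, pos = as.integer(raw$V4),
    state = ifelse(raw$V5 %chin% c("Z", "M"), "M",
                   ifelse(raw$V5 %chin% c("z", "u", "U"), "U", NA_character_))
  )
  if (anyNA(calls$state) || anyNA(calls$pos)) {
    stop(sprintf("malformed read-level call at line %d of %s",
                 which(is.na(calls$state) | is.na(calls$pos))[1L], path))
  }
  normalize_read_calls(calls, min_cpgs = min_cpgs, collapse = collapse,
                       cpg_sites = cpg_sites)
}

#' @rdname read_readlevel_calls
#' @param calls a raw call table (read_id, chrom, pos, state)
#' @export
normalize_read_calls <- function(calls, min_cpgs = 3L, collapse = TRUE,
                                 cpg_sites = NULL) {
  calls <- data.table::as.data.table(calls)
  if (collapse && !is.null(cpg_sites)) {
    calls[, pos := {
      sites <- cpg_sites[[chrom[1L]]]
      if (is.null(sites)) pos
      else ifelse(!(pos %in% sites) & (pos - 1L) %in% sites, pos - 1L, pos)
    }, by = chrom]
  }
  n_chrom <- calls[, data.table::uniqueN(chrom), by = read_id]
  if (any(n_chrom$V1 > 1L)) {
    warning(sprintf("%d read id(s) span multiple chromosomes; split per chromosome",
                    sum(n_chrom$V1 > 1L)))
  }
  calls <- unique(calls, by = c("read_id", "chrom", "pos"))
  calls[, n_calls := .N, by = .(read_id, chrom)]
  calls <- calls[n_calls >= min_cpgs][, n_calls := NULL]
  data.table::setorder(calls, chrom, read_id, pos)
  calls[]
}

#' Write read-level CpG calls
#' @param calls read-call table
#' @param path output path
#' @export
write_read_calls <- function(calls, path) {
  writeLines("# methcompare read-level CpG calls: read_id, state_flag, chrom, pos (1-based, plus-strand C), call (Z=methylated, z=unmethylated)",
             path)
  out <- calls[, .(read_id, flag = ifelse(state == "M", "+", "-"), chrom, pos,
                   call = ifelse(state == "M", "Z", "z"))]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

build_gene_models <- function(tx) {
  # tx: data.table(transcript_id, gene_id, name, chrom, strand, start, end)
  genes <- tx[, .(name = name[1L], chrom = chrom[1L], strand = strand[1L],
                  start = min(start), end = max(end)), by = gene_id]
  genes[, tss := ifelse(strand == "+", start, end)]
  data.table::setorder(genes, chrom, start)
  genes[]
}

#' Load gene and region annotations into one bundle
#'
#' Accepts genes as GTF (1-based inclusive) or BED12 (0-based half-open,
#' converted on read); CGI/repeat/exclusion annotations as BED. Gene models
#' merge all isoforms of a gene into one annotation (union of transcript
#' spans); per-transcript TSS are retained for promoter selection. With a
#' genome, annotation entries on unknown chromosomes are skipped with a
#' warning and per-CGI CpG counts are precomputed.
#'
#' @param genes path to GTF/BED12, or a transcripts data.table with columns
#'   transcript_id, gene_id, name, chrom, strand, start, end (1-based)
#' @param cgis,repeats,exclusions BED paths or GRanges (optional)
#' @param genome DNAStringSet or FASTA path (optional)
#' @param exons optional exon data.table (gene_id, transcript_id, chrom,
#'   start, end) when `genes` is a data.table
#' @return list with genes, transcripts, exons (data.tables), cgis, repeats,
#'   exclusions (GRanges), chrom_lengths, cpg_sites
#' @export
load_annotations <- function(genes, cgis = NULL, repeats = NULL,
                             exclusions = NULL, genome = NULL, exons = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))

  if (is.character(genes)) {
    gr <- rtracklayer::import(genes)
    if (!is.null(S4Vectors::mcols(gr)$type)) { # GTF
      txgr <- gr[S4Vectors::mcols(gr)$type %in% c("transcript", "mRNA")]
      exgr <- gr[S4Vectors::mcols(gr)$type == "exon"]
      tx <- data.table::data.table(
        transcript_id = S4Vectors::mcols(txgr)$transcript_id,
        gene_id = S4Vectors::mcols(txgr)$gene_id,
        name = S4Vectors::mcols(txgr)$gene_name %||% S4Vectors::mcols(txgr)$gene_id,
        chrom = as.character(GenomicRanges::seqnames(txgr)),
        strand = as.character(GenomicRanges::strand(txgr)),
        start = GenomicRanges::start(txgr), end = GenomicRanges::end(txgr))
      exons <- data.table::data.table(
        gene_id = S4Vectors::mcols(exgr)$gene_id,
        transcript_id = S4Vectors::mcols(exgr)$transcript_id,
        chrom = as.character(GenomicRanges::seqnames(exgr)),
        start = GenomicRanges::start(exgr), end = GenomicRanges::end(exgr))
    } else { # BED12: one transcript per line, blocks are exons
      tx <- data.table::data.table(
        transcript_id = S4Vectors::mcols(gr)$name,
        gene_id = S4Vectors::mcols(gr)$name,
        name = S4Vectors::mcols(gr)$name,
        chrom = as.character(GenomicRanges::seqnames(gr)),
        strand = as.character(GenomicRanges::strand(gr)),
        start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
      blk <- S4Vectors::mcols(gr)$blocks
      if (!is.null(blk)) {
        exl <- lapply(seq_along(gr), function(i) {
          b <- blk[[i]]
          data.table::data.table(
            gene_id = tx$gene_id[i], transcript_id = tx$transcript_id[i],
            chrom = tx$chrom[i],
            start = tx$start[i] + GenomicRanges::start(b) - 1L,
            end = tx$start[i] + GenomicRanges::end(b) - 1L)
        })
        exons <- data.table::rbindlist(exl)
      }
    }
  } else {
    tx <- data.table::as.data.table(genes)
    stopifnot_cols(tx, c("transcript_id", "gene_id", "chrom", "strand",
                         "start", "end"), "transcripts table")
    if (is.null(tx$name)) tx[, name := gene_id]
  }
  tx[, tss := ifelse(strand == "+", start, end)]

  as_bed_gr <- function(x) {
    if (is.null(x)) return(GenomicRanges::GRanges())
    if (methods::is(x, "GRanges")) return(x)
    rtracklayer::import(x, format = "BED")
  }
  cgis <- as_bed_gr(cgis); repeats <- as_bed_gr(repeats)
  exclusions <- as_bed_gr(exclusions)

  chrom_lengths <- NULL; cpg_sites <- NULL
  if (!is.null(genome)) {
    chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
    cpg_sites <- cpg_sites_from_genome(genome)
    drop_unknown <- function(gr, what) {
      bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(genome))
      if (any(bad)) {
        warning(sprintf("%d %s interval(s) on unknown chromosomes skipped",
                        sum(bad), what))
      }
      gr[!bad]
    }
    cgis <- drop_unknown(cgis, "CGI")
    repeats <- drop_unknown(repeats, "repeat")
    exclusions <- drop_unknown(exclusions, "exclusion")
    badtx <- !(tx$chrom %in% names(genome))
    if (any(badtx)) {
      warning(sprintf("%d transcript(s) on unknown chromosomes skipped", sum(badtx)))
      tx <- tx[!badtx]
    }
    if (length(cgis)) {
      S4Vectors::mcols(cgis)$n_cpg <- count_cpgs_in(cgis, cpg_sites)
    }
  }
  if (length(cgis) && is.null(S4Vectors::mcols(cgis)$cgi_id)) {
    S4Vectors::mcols(cgis)$cgi_id <- sprintf("cgi_%04d", seq_along(cgis))
  }

  list(genes = build_gene_models(tx), transcripts = tx[],
       exons = if (!is.null(exons)) data.table::as.data.table(exons) else NULL,
       cgis = cgis, repeats = repeats, exclusions = exclusions,
       chrom_lengths = chrom_lengths, cpg_sites = cpg_sites)
}

# number of genomic CpG sites inside each interval of a GRanges
count_cpgs_in <- function(gr, cpg_sites) {
  vapply(seq_along(gr), function(i) {
    sites <- cpg_sites[[as.character(GenomicRanges::seqnames(gr)[i])]]
    if (is.null(sites)) return(0L)
    sum(sites >= GenomicRanges::start(gr)[i] & sites <= GenomicRanges::end(gr)[i])
  }, integer(1))
}
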