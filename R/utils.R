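# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rolling mean with partial windows at the edges
#'
#' Centred window of `k` values; at chromosome ends the mean is taken over
#' the values actually available (no NA padding), so every position gets a
#' smoothed value.
#' @param x numeric vector
#' @param k odd window size (k = 1 returns x)
#' @return numeric vector of length(x)
#' @keywords internal
smooth_partial <- function(x, k = 3L) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# data.table (chrom, start, end, ...) -> GRanges, 1-based closed in and out
dt_to_gr <- function(dt, keep = character()) {
  if (nrow(dt) == 0L) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end))
  for (col in keep) S4Vectors::mcols(gr)[[col]] <- dt[[col]]
  gr
}

gr_to_dt <- function(gr) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) dt <- cbind(dt, data.table::as.data.table(mc))
  dt
}

# GRanges for gene bodies from a genes data.table
genes_gr <- function(genes) {
  dt_to_gr(genes, keep = intersect(c("gene_id", "name", "strand", "tss"), names(genes)))
}

# per-CpG GRanges (width-1 anchored at the plus-strand C)
cpg_gr <- function(cpg) {
  GenomicRanges::GRanges(cpg$chrom, IRanges::IRanges(cpg$pos, cpg$pos))
}

stopifnot_cols <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# maximal runs of TRUE; returns data.table(from, to) of 1-based indices
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.table::data.table(from = starts[r$values], to = ends[r$values])
}
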