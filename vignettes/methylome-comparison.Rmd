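---
title: "Comparative methylome analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative methylome analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `methcompare`, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where the design was open.

## Inputs and conventions

The package consumes post-alignment WGBS products: per-CpG coverage tables
in the Bismark `.cov` dialect (1-based positions, counts of methylated and
unmethylated calls) and read-level CpG call tables in the CpG-context
dialect (read id, chromosome, position, Z/z call). Internally all
coordinates are 1-based closed intervals on the GenomicRanges stack;
conversion from the 0-based half-open BED convention happens only at I/O.
Every CpG is keyed by the position of the C on the plus strand; calls on
the minus strand are folded onto that C (`combine_strands()`), duplicate
records are summed, and methylation is carried as a percent in [0, 100]
(segmentation math converts to fractions explicitly). The standard filters
are a minimum depth of 5 calls per CpG (10 for RRBS-style data) and, for
read-level work, at least 3 CpG calls per read.

## CpG density and classification

CpG density is the observed/expected ratio
$\mathrm{o/e} = (n_{\mathrm{CpG}} \times L)/(n_C \times n_G)$, with N bases
excluded from every count and a declared value of 0 when the denominator
vanishes. It is applied to 0.5-kb sliding windows (windows over 50% N are
dropped) and to promoter windows $[\mathrm{TSS}-1000, \mathrm{TSS}+500)$,
strand-oriented; when a gene has several annotated TSS the promoter with
the highest ratio is kept. Promoters are classed LCP (ratio below a lower
cutoff), HCP (ratio above an upper cutoff *and* GC above 55%), else ICP.
The cutoffs are species-specific inputs because the bimodality of the
promoter-ratio distribution sits at different ratios in different genomes;
`suggest_promoter_cutoffs()` proposes values from the antimodes of the
kernel density but is never applied silently.

CGIs (an input annotation, not called de novo) are classed by the
unweighted mean over their covered CpGs: unmethylated below 10%, low in
[10, 50], high above 50, with class `NA` when fewer than 35% of the CGI's
genomic CpGs are covered. Means are unweighted rather than
coverage-weighted to keep the statistic independent of local depth; a
`weighted` switch restores coverage weighting.

## Segmentation

UMRs are maximal runs of at least 5 consecutive CpGs whose smoothed
methylation fraction is below 0.5. Smoothing is a centred 3-CpG rolling
mean with partial windows at chromosome ends (every CpG gets a value;
`smooth_k = 1` disables it). Runs span first to last CpG and never bridge
a CpG masked by a PMD. DMVs are UMRs at least 5 kb long, inclusive.

PMD detection is a deliberately transparent approximation of HMM-based
segmenters: a CpG is flagged when more than half of the CpGs in its
centred 101-CpG window have methylation in the intermediate band
[0.3, 0.7]; flagged windows are expanded to their spans, merged across
gaps up to 5 kb, and intervals below 10 kb are discarded. The size floor
encodes that PMDs are large domains — without it every ~50%-methylated
CpG island (an imprinted locus, for instance) is flagged as a tiny PMD.
Two limitations follow: ~50%-methylated regions longer than the floor
(such as the multi-kilobase imprinted CGIs in the simulation, and an
X chromosome whose non-CGI background sits near 60%) are still absorbed,
and the genome fractions this approximation covers are not comparable to
HMM-based estimates on real data. The approximation is therefore validated
only against synthetic truth (Jaccard > 0.8 on implanted domains), and
`detect_umrs()` accepts externally produced PMD intervals so an exact
reproduction path remains open.

## Read-level allelic DMR prediction

Imprinted (germline) DMRs show ~50% aggregate methylation because one
parental allele is methylated and the other is not; random partial
methylation can produce the same aggregate. The discriminator is the
single-read methylation pattern: allelic loci contain a mixture of fully
methylated and fully unmethylated molecules. The scan divides the genome
into 50-bp windows sliding by 10 bp; a read overlaps a window when at
least one of its CpG calls falls inside, and its fully-called status is
judged over *all* of its calls — per-window re-evaluation would let a
1-call overlap count as "fully" methylated by accident. A window passes
when (i) its mean methylation over the coverage table's CpGs lies in
[30, 60]%, (ii) more than 90% of its reads are fully methylated or fully
unmethylated, and (iii) the difference between the fully-methylated and
fully-unmethylated percentages is below 40 (balance between alleles). A
minimum of 5 reads per window (configurable; 1 restores a literal
reading of the gates) suppresses single-read windows. Window mean
methylation comes from the aggregated CpG table by default; a
`meth_source = "reads"` switch uses in-window read calls instead.

Passing windows are merged with interval semantics (overlapping or
book-ended windows union, as `bedtools merge` would), candidates on chrX
are removed (XCI produces exactly this read-level signature), candidates
overlapping a developmental-gene exclusion list are removed, and the mode
gates apply: stringent keeps regions larger than 350 bp (strict) with at
least 20 distinct covered CpGs, lenient keeps regions with at least 10
CpGs. Candidates are assigned to the nearest gene within 50 kb (the
association distance is not pinned down by any external definition;
50 kb is configurable) and aggregated across species by ortholog, ranked
by species count and then by stringent-call count.

At 12X coverage the per-window gates are noisy (a window holds ~2–8 CpGs
whose percents each carry binomial error), so a multi-kilobase allelic
locus is recovered as several sub-kilobase fragments rather than one
block. That is why the stringent gate's 350-bp/20-CpG thresholds operate
per fragment, and why sensitivity is assessed as truth loci hit by at
least one stringent call.

## X-inactivation escape

Promoter-CGI methylation predicts XCI status: subject genes carry
~30%-methylated promoter CGIs on the inactive X while escapees stay below
10%. `call_escapees()` applies the strict 10% threshold to X-linked genes
whose promoter CGI passes the 35% coverage rule; X-vs-autosome contrasts
use two-sided Wilcoxon rank-sum tests (normal approximation with tie
correction — the exact test is unavailable with ties and adds nothing at
these sample sizes) on promoter-CGI means and on non-CGI 1-kb tiles
(non-overlapping, fully contained in the chromosome, excluded when they
touch a CGI by even 1 bp). Escapee calling is annotation-limited: a gene
without an annotated promoter CGI is not callable, and no genome-browser
rescue of unannotated promoters is attempted.

## Enrichment

`hypergeom_enrichment()` computes the upper tail $P(X \ge k)$ for drawing
$k$ target genes in a selection of size $n$ from a background of size $N$
containing $K$ targets, plus the fold enrichment $(k/n)/(K/N)$; p-values
are adjusted by Benjamini–Hochberg. "Methylated CpG-rich promoter" is
operationalized as an ICP/HCP promoter with mean methylation above 50%.
The engine is generic: any term-to-gene table can be supplied, and no
ontology is bundled.

## The synthetic study

The generator emulates the statistical structure the analyses assume, with
truth labels for parameter recovery. The reference conditions, fixed once:

* three species, each with two 700-kb autosomes and a 600-kb chrX
  (~2 Mb), identical layouts across species so orthology follows gene
  order (`og_<chrom>_<index>`), with independent sequences and reads;
* background sequence with CG thinned to o/e ≈ 0.4 (GC 42%); CGIs sampled
  at GC 60%, o/e ≈ 1; ~32 genes per autosome, each with an 800-bp promoter
  CGI; every fifth gene has a second isoform with a shifted TSS;
* a two-allele methylome: autosomal background 0.80 per allele, chrX
  non-CGI background 0.60, repeats 0.90, promoter CGIs 0.03, three ≥ 5-kb
  valleys at 0.02 over designated developmental genes, ten imprinted loci
  per species at kilobase-scale promoter CGIs with read-coherent alleles
  (1.0, 0.0), X subject promoter CGIs at (0.55, 0.05) — ~30% aggregate —
  and three escapees at 0.02, one 50-kb gene desert per autosome flagged
  for per-read random partial methylation (level uniform on [0.2, 0.8]);
* reads: Poisson placement at 12X mean CpG depth, 100-bp single molecules,
  allele drawn per read with equal probability, each call flipped with
  probability 0.005 (residual bisulfite error); the coverage table is the
  exact aggregation of the emitted calls;
* six germline genes with methylated CpG-rich promoters implanted as
  upregulated (fold change 6–24, tiny adjusted p) in a simulated
  differential-expression table, plus eight methylated-promoter background
  genes so the methylated-promoter background is non-trivial.

Two generator choices deserve justification. First, imprinted alleles are
fully coherent (1.0/0.0) with noise carried entirely by the per-call error
flip: with ~9 CpG calls per read inside a CGI, an allele probability of
0.95 would make "fully methylated" reads a minority (0.95^9 ≈ 0.63) and no
read-level bimodality gate could behave as it does on real germline DMRs,
where the methylated epiallele is maintained coherently. Second, implanted
imprinted CGIs span 5 kb — the scale of real germline DMR CGIs — because
at 12X the window gates fragment candidates into ~300–600-bp pieces;
sub-kilobase truth loci would test the fragment-size gate, not the caller.
Random partial methylation is modelled per read (not per allele) precisely
so the allelic/partial discrimination claim is testable. Germline and
methylated-background promoters are CpG-rich in sequence but absent from
the CGI annotation track, as methylated CpG-rich promoters often are in
real CGI tracks.

What the generator does not emulate — and what passing tests therefore do
not show about real data: sequence-level reads (no FASTQ, no instrument
error profiles, no PCR duplicates, no mappability structure), paired-end
fragment geometry (a read is one molecule's CpG calls), non-CpG
methylation, spatially correlated coverage, cell-type heterogeneity, and
genuine evolutionary divergence (orthology is exact by construction, so
conservation statistics recover 100% rather than realistic intermediate
values).

## Numerical choices and degenerate inputs

The CpG ratio of a window with no Cs or no Gs is 0 by convention; empty
sequences are errors. Coverage records whose stored percent disagrees with
the counts by more than 0.5 lose to the counts, with a warning. Windows
with no covered CpG have `NA` mean methylation and fail the allelic mean
gate. Chromosomes with fewer CpGs than the PMD window yield no PMD call,
with a warning. Promoter windows truncated at contig ends are flagged.
Proportions are always reported over non-NA classes and sum to 100.
Determinism relies on R's default RNG with integer seeds only; the full
pipeline writes byte-identical outputs when re-run with the same seed.

## Problem sizes

The reference study (three ~2-Mb species at 12X, ~44,000 CpGs and
~530,000 read calls per species) was chosen so that a full simulate →
analyse → aggregate cycle completes in under half a minute on one CPU
while every implanted regime keeps enough loci (30 imprinted, 9 valleys,
9 escapees, 6 domains) for recovery rates to be meaningful. The same code
paths handle genome-scale inputs; the data.table/GenomicRanges operations
scale linearly in calls and CpGs.
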