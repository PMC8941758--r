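# Simulate the reference study: three species with conserved gene order,
# ~2 Mb genomes (two autosomes + chrX), two-allele methylomes and 12X
# bisulfite reads, and write the post-alignment products (FASTA, GTF, BEDs,
# coverage and read-level call tables, truth labels) under results/sim/.
source("analysis/_common.R")

study <- get_study()

for (sp in names(study$species)) {
  b <- study$species[[sp]]
  write_simulation(b, dir_create("results", "sim", sp))
  cat(sprintf(
    "%s: %d chromosomes, %d genes, %d CGIs, %s CpGs, %s read calls (mean depth %.1fX)\n",
    sp, length(b$genome), nrow(b$annotations$genes),
    length(b$annotations$cgis),
    format(nrow(b$cov), big.mark = ","),
    format(nrow(b$calls), big.mark = ","), mean(b$cov$n_total)))
}
fwrite(study$ortholog_map, "results/sim/ortholog_map.tsv", sep = "\t")
cat("truth per species: 10 imprinted DMRs, 3 valleys (>=5 kb), 2 PMDs,",
    "3 XCI escapees, 6 germline genes\n")
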