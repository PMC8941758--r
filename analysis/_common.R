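# Shared setup for the analysis scripts. Run every script from the
# repository root, e.g.  Rscript analysis/01_simulate.R
suppressMessages({
  library(methcompare)
  library(data.table)
})

SEED <- 1L
CONFIG <- default_config(seed = SEED)

dir_create <- function(...) {
  p <- file.path(...)
  dir.create(p, recursive = TRUE, showWarnings = FALSE)
  p
}

# The simulated study is rebuilt deterministically from SEED and cached on
# disk so the downstream scripts do not re-simulate.
get_study <- function() {
  cache <- file.path("results", "sim", "study.rds")
  if (file.exists(cache)) return(readRDS(cache))
  study <- simulate_study(n_species = CONFIG$n_species, seed = SEED,
                          spec = CONFIG$methylome)
  for (sp in names(study$species)) {
    b <- study$species[[sp]]
    study$species[[sp]]$annotations$exclusions <-
      methcompare:::dt_to_gr(
        b$annotations$genes[gene_id %in% b$truth$valleys$gene_id])
  }
  dir_create("results", "sim")
  saveRDS(study, cache)
  study
}
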