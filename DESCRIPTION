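Package: methcompare
Title: Comparative Analysis of Vertebrate DNA Methylomes from Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative whole-genome bisulfite sequencing analysis:
    CpG-density landscapes (observed/expected CpG-ratio windows, promoter and
    CpG-island classification), segmentation of unmethylated regions, DNA
    methylation valleys and partially methylated domains, read-level prediction
    of allelic (imprinted) differentially methylated regions, X-inactivation
    escapee prediction from promoter CpG-island methylation, cross-species
    ortholog conservation statistics, and hypergeometric gene-set enrichment.
    Includes a synthetic methylome and bisulfite-read generator with ground-truth
    labels for validating every step, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
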