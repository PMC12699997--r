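Package: phylocap
Title: Target-Capture Phylogenomics: Marker Selection, Bait Design, Capture
    QC and Multilocus Barcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building and using target-enrichment marker sets in
    phylogenomics. Selects representative sequences per locus by k-medoids
    clustering with a coverage-fraction convergence criterion, designs tiled
    80 bp hybridization baits with GC, repeat, residual-N and multi-genome
    multi-hit filters, runs stepwise gene-addition saturation analyses
    (normalized Robinson-Foulds distance and mean bootstrap support against a
    reference topology), filters multi-copy capture extractions by coverage
    depth ratio, and performs distance-skim multilocus barcoding with
    neighbor selection capped per species. Includes an internal
    neighbor-joining and bootstrap engine, Robinson-Foulds and concordance
    machinery, modified Thompson-tau outlier removal, MDS plus density-based
    topology clustering, and a Yule/JC69 synthetic-data simulator so every
    component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
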