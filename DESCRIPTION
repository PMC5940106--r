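Package: cpglife
Title: Phylogenetic Regression of Promoter CpG Density on Species Lifespan
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale comparative analysis of promoter CpG
    dinucleotide density against species maximum lifespan. Implements
    phylogenetic generalized least squares (PGLS) with Pagel's lambda
    estimated by profiled maximum likelihood, readers for homology hit
    tables in a 14-column BLAST tabular dialect, best-hit-per-species
    culling with identity tiers, CpG and GC composition statistics,
    Benjamini-Hochberg control across loci, direction-skew and gene-set
    overlap summaries, and a truth-tagged synthetic data generator (Yule
    trees, Brownian-motion lifespans, sequences with exact CpG counts) for
    end-to-end validation without genome downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    yaml,
    optparse
Config/testthat/edition: 3
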