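Package: rloopscape
Title: R-Loop Landscape Analysis for DRIP-Seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of DRIP-seq R-loop landscapes in genomes
    with a single X chromosome arm. Implements chromosome- and
    width-preserving interval shuffling with permutation-based
    feature/chromatin-state enrichment and Benjamini-Hochberg correction,
    exact binomial tests of X-versus-autosome peak density,
    sequencing-depth downsampling with a window-Poisson stand-in peak
    caller, scale-regions metagene profiling, IUPAC consensus motif
    scanning with per-megabase X:autosome density ratios, sex-biased peak
    class summaries, and rank-sum group comparisons. A seeded synthetic
    data generator emulates a five-arm Drosophila-like genome with
    X-enriched peak density, a five-colour chromatin-state partition, gene
    models, and expression tables so that every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
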