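Package: g4peaks
Title: G-Quadruplex Enrichment Analysis in Transcription-Factor Binding Sites
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying putative G-quadruplex sequence (PQS)
    enrichment in ChIP-seq binding-site sets. Implements G4Hunter
    sliding-window scoring and PQS calling, interval algebra between PQS
    and peak sets, promoter and biotype annotation, a Markov-chain
    genome-randomization null with replicate-based enrichment statistics,
    a p53 response-element consensus scanner, and the statistical chain
    for yeast luciferase reporter assays (RLU normalization, Tukey
    fencing, fold-of-empty, two-way ANOVA with Dunnett comparisons).
    Ships a fully parameterized synthetic-data generator with ground-truth
    manifests for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rcpp,
    car,
    methods,
    mvtnorm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
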