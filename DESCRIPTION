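Package: famscan
Title: Genome-Wide Gene Family Mining, Molecular Evolution and Expression
    Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for characterizing a receptor-kinase gene
    family from genome-scale inputs: candidate identification from domain
    architecture (lectin + transmembrane + kinase), subfamily classification,
    protein and gene-structure statistics (molecular weight, isoelectric
    point, exon/intron counts), Poisson-corrected neighbor-joining
    phylogenies with bootstrap support, duplication-event detection with
    tandem clustering, Nei-Gojobori Ka/Ks estimation and divergence dating,
    promoter cis-element scanning against an IUPAC motif catalog, FPKM
    expression profiling, and 2^-ddCt qPCR fold-change calling. Includes a
    synthetic-data generator that plants known truth for every stage so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
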