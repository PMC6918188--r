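Package: creFingerprint
Title: Regulatory Fingerprints of Cis-Regulatory Elements from Expression
    Meta-Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide significance analysis of cis-acting regulatory
    elements (CREs). Scans gene-flanking regions (1 kb / 3 kb upstream,
    5'-UTR, introns, 1 kb downstream) for IUPAC degenerate motifs with
    PATMATCH-style semantics, tests each motif's association with gene
    regulation by chi-squared enrichment of two-fold induced and suppressed
    genes across a multi-array expression meta-matrix (the "regulatory
    fingerprint"), stratifies significance by motif position, orientation
    and copy number, discovers novel and co-existing motifs with a ZOOPS
    Gibbs sampler over an order-k Markov background, and predicts
    associated transcription factors by correlating gene-set z-score
    profiles with TF expression. Ships a synthetic-data generator with
    full ground truth so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
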