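Package: hoofprint
Title: Selection Signatures in Livestock Genomes via iHS and Runs of Homozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects footprints of recent selection in dense diploid genotype
    panels. Implements extended haplotype homozygosity (EHH) decay curves,
    integrated haplotype homozygosity and the standardized integrated
    haplotype score (iHS) with windowed top-quantile candidate-region calling;
    a PLINK-style sliding-window detector for runs of homozygosity (ROH) with
    length-class summaries and population-level ROH-island calling; genomic
    inbreeding coefficients (diagonal of the genomic relationship matrix,
    excess homozygosity, and correlation between uniting gametes); and
    interval annotation of candidate regions against gene, QTL and eQTL
    tables. A seeded haplotype simulator with partial hard sweeps and
    exponential autozygosity tracts provides ground truth for recovery tests,
    and a configuration-driven pipeline runs every stage end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
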