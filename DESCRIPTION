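Package: archscan
Title: Reference-Free Archaic Introgression Scans and Founder-Event
    Statistics for Phased Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects archaic (Neanderthal and Denisovan) introgressed
    segments in phased diploid genomes without an archaic reference, using
    a two-state hidden Markov model with Poisson emissions on windowed
    private-derived-variant counts. Assigns segment sources by derived
    archaic variant match rates, assembles per-population introgressed
    genomes with sharing partitions and rarefaction curves, scans the
    archaic-frequency landscape for enriched regions, deserts, population
    branch statistic outliers and uniquely shared derived alleles,
    converts the human-state emission rate into a minimum coalescence
    time with an outgroup, and computes identity-by-descent founder-event
    statistics with closed-form cousin expectations. A synthetic-data
    generator produces phased cohorts with known introgressed tracts,
    archaic reference genomes, outgroup panels and pedigree cousin pairs
    for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    vcfR,
    mclust,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
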