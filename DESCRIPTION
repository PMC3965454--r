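Package: ibdscreen
Title: Opposite-Homozygosity Filtering for Fast Identity-by-Descent
    Candidate Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens a database of unphased diploid biallelic genotypes for
    segments that may be identical by descent (IBD) with a query individual.
    A per-marker index of homozygous-individual sets supports a sliding
    genetic-map window scan in which opposite-homozygous markers exclude
    (individual, segment) pairs, with a binomial genotyping-error tolerance
    model that converts a per-window false-removal bound into a maximum
    tolerated opposite-homozygote count, and optional Jaccard-label pruning of
    redundant markers in linkage disequilibrium. Includes readers and writers
    for VCF and PLINK text genotypes, a synthetic cohort simulator (mosaic
    composite haplotypes, injected IBD segments, per-allele genotyping
    errors), and an evaluation harness computing sensitivity, candidate
    fraction, speedup and Pareto frontiers over error-threshold sweeps.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml,
    optparse,
    vcfR
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
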