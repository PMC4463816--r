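Package: sweepscan
Title: Selection Scans from Phased Genotypes with Empirical-Outlier Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome scans for recent positive selection from phased biallelic
    genotypes: extended haplotype homozygosity (EHH), the integrated haplotype
    score (iHS), cross-population EHH (XP-EHH), the Weir-Cockerham fixation
    index and the population branch statistic (PBS), together with the
    fixed-window empirical-outlier framework used in SNP-array selection
    studies (SNP-count binning, top-percentile calling, cross-population
    exclusion, cross-test overlaps) and candidate-gene / GO-term enrichment
    via the conservative EASE score. Includes a seedable synthetic-data
    generator (Balding-Nichols drift on a population tree, founder-copying
    linkage disequilibrium, selective-sweep injection) so the whole pipeline
    can be exercised and calibrated without genotype downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
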