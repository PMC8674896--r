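Package: trihybrid
Title: Diagnostic SNP Panels and Hybrid Classification for Three-Lineage
    Admixture Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing hybrid zones among three diverged
    diploid lineages from biallelic SNP genotypes: post-calling SNP quality
    control (minor-allele, missingness, Hardy-Weinberg and linkage
    disequilibrium filters), Nei-Chesser diversity statistics and
    Weir-Cockerham F_ST, maximum-likelihood supervised and unsupervised
    admixture ancestry estimation, diagnostic SNP panel design by iterative
    subset search against full-data ancestry, Mendelian simulation of pure,
    F1, later-generation, backcross and triple-hybrid genotypes with
    efficiency/accuracy/performance evaluation of Q-threshold assignment
    rules, and fractional logistic regression of introgressed ancestry on
    great-circle distance and stocking history. Includes a seedable
    synthetic-data generator (Balding-Nichols lineages with planted fixed
    differences calibrated to target F_ST) so the whole pipeline can be
    exercised without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    geosphere,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
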