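Package: kccu
Title: Gene-Based Gene-Gene Co-Association Tests via Kernel Canonical
    Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-based tests for gene-gene co-association in case-control
    studies. Implements the CCU statistic (difference of Fisher-transformed
    first canonical correlations between two SNP sets in cases versus
    controls, scaled by bootstrap variances) and its kernel counterpart KCCU
    based on regularized kernel canonical correlation analysis, together
    with permutation p-values, a pairwise logistic-regression comparator, a
    two-locus multiplicative-interaction genotype simulator with synthetic
    haplotype pools, and a config-driven harness for type-I-error and power
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
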