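Package: scurmap
Title: QTL Mapping of Categorical Horn Traits by Combined Linkage
    Disequilibrium and Linkage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variance-component QTL mapping of ordered categorical traits
    such as scurs in polled cattle. Provides liability-scale and binary
    codings of horn phenotypes, genomic and leave-one-chromosome-out
    relationship matrices, haplotype sliding-window identity-by-descent and
    diplotype relationship matrices at SNP-interval midpoints, an
    average-information REML engine for one- and two-variance-component
    mixed models, likelihood-ratio genome scans with empirical permutation
    significance thresholds, GREML SNP-heritability estimation with
    permutation validation, mixed linear model association with
    leave-one-chromosome-out control, and a liability-threshold power
    simulation. Includes a founder-mosaic simulator of phased haplotype
    panels and categorical phenotypes with known QTL architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
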