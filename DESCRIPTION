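Package: salicoloc
Title: Multi-Trait GWAS Colocation Analysis for Reproductive-Stage
    Salinity Tolerance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for windowed multi-trait GWAS
    colocation analysis in inbred diversity panels under salinity
    stress: simulation of block-LD genotype panels with planted
    treatment-specific QTLs, relative-trait derivation (saline/control
    ratios), an OLS association scan with principal-component
    covariates, MAF filtering and LD pruning, an effective-test-number
    genome-wide threshold, a windowed peak-colocation enrichment test
    with a binomial/normal null, and haplotype-group favourability
    ranking within colocating loci.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
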