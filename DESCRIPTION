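Package: ailnet
Title: Epistatic QTL Network Analysis for Advanced Intercross Lines
Version: 0.1.0
Authors@R: person("ailnet", "maintainers", email = "ailnet@example.org", role = c("aut", "cre"))
Description: Tools for dissecting multi-locus epistatic networks affecting a
    quantitative trait in an advanced intercross line (AIL) between two
    divergently selected founder lines. Includes a gene-dropping AIL
    simulator with configurable epistatic genotype-phenotype architectures,
    line-origin contrast discretization and genotype stratification,
    two-locus epistatic model scans with bootstrap-averaged one-dimensional
    profiles and permutation-derived study-wide thresholds, stratified
    additive-effect estimation with network-level summaries and k-level
    multi-locus effect decomposition, model-free and orthogonal (NOIA)
    genotype-phenotype maps, and a plane-variance ratio statistic (R_p) for
    detecting third-order capacitating epistasis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
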