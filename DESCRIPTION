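Package: snpblup
Title: Genomic Evaluation and Association Testing with GBLUP and Single-Step GBLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale quantitative-genetics toolkit for genomic evaluation and
    genome-wide association. Builds pedigree (A) and genomic (G) relationship
    matrices and their inverses, including the combined single-step matrix H,
    assembles and solves Henderson's mixed-model equations, estimates variance
    components by EM-REML, and derives formal per-SNP association tests by
    back-solving SNP effects from (G)EBV with exact prediction-error variances.
    Includes jackknife confidence intervals for QTL peak positions, window-based
    QTL variance estimation, higher-order linkage-disequilibrium and
    selection-theory calculators, and a gene-dropping population simulator so
    that every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
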