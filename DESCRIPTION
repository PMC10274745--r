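Package: xydosage
Title: Modeling Autosomal Expression Responses to Sex Chromosome Dosage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how autosomal gene expression responds to
    X and Y chromosome copy number. Fits per-gene negative-binomial
    log-linear models of read counts against chromosome dosage (or arbitrary
    designs) with median-of-ratios normalization, method-of-moments
    dispersion estimation, Wald tests and Benjamini-Hochberg correction;
    harmonizes heterogeneous allelic-ratio studies into X-inactivation
    escape calls; compares response vectors with weighted Deming
    (errors-in-variables) regression, hypergeometric overlap and gene-set
    enrichment tests; quantifies Yq heterochromatin length from GC-corrected
    read-depth ratios; and projects samples by PCA with karyotype-group
    confidence ellipses. A synthetic-data generator with known ground truth
    emulates the cohort, allelic-ratio and depth-of-coverage inputs so that
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
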