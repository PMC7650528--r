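Package: scMethylDeconv
Title: DNA Methylation Reference Imputation from Single-Cell Expression
    and Cell-Type Deconvolution of Bulk Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds tissue-specific DNA methylation reference matrices from
    clustered single-cell RNA-seq atlases via a probabilistic model of the
    expression to promoter/enhancer methylation relationship, and uses the
    imputed reference for weighted robust cell-type deconvolution of bulk
    DNA methylation profiles and for detection of cell-type-specific
    differential methylation through a fraction-by-phenotype interaction
    model. Includes marker selection from clustered single-cell data,
    genome-wide scans for genes whose regulatory-element methylation is
    predictable from expression, a two-state gamma-mixture expression model
    fitted by EM, in-silico mixture simulation, and seeded synthetic-data
    generators for every input class.
License: GPL-2
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Matrix,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
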