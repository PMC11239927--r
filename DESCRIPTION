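Package: phenocurate
Title: Curation of Multi-Year Genebank Phenotype Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for curating historical phenotypic records from genebank
    regeneration trials. Fits a two-way mixed model (accession by year) by
    restricted maximum likelihood with year-specific residual variances,
    screens outliers with MAD-rescaled standardized residuals under
    Bonferroni-Holm family-wise error control, computes per-accession best
    linear unbiased estimates (BLUEs), entry-mean heritability, and
    descriptive provenance and coverage summaries. Includes a generator of
    non-orthogonal, heteroscedastic multi-year trial datasets with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
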