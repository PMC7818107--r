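Package: gscapower
Title: Candidate-Gene Association by Generalized Structured Component
    Analysis with Monte-Carlo Power Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits gene-level association models by generalized structured
    component analysis (GSCA): each gene is a unit-variance weighted sum of
    its SNP dosages, the clinical outcome is a weighted sum of quantitative
    phenotypes, and structural paths linking genes to the outcome are
    estimated by alternating least squares and tested by permutation.
    Includes the standard per-SNP regression comparator with
    multiple-testing correction, a synthetic-data generator with
    linkage-disequilibrium-structured SNP blocks and planted SNP-phenotype
    correlations, and a Monte-Carlo engine estimating statistical power and
    false-positive rates over scenario grids.
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
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
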