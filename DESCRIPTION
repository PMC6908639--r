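Package: telodyn
Title: Pedigree-Based Analysis of Leukocyte Telomere Length Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying diet-induced leukocyte telomere length (LTL)
    dynamics in pedigreed animal colonies. Covers the full analysis chain
    from qPCR plate exports to quantitative-genetic inference: telomere to
    single-copy-gene (T/S) quantification via per-plate standard curves,
    recursive pedigree kinship matrices, maximum-likelihood polygenic
    variance decomposition with likelihood-ratio tests for covariates and
    for heritability on the boundary, rank-based inverse normal
    transformation, residual-based telomere attrition (delta-LTL), exact
    permutation Wilcoxon-Mann-Whitney median tests, and biomarker/lesion
    association tables. Includes a synthetic pedigree-and-phenotype
    generator so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
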