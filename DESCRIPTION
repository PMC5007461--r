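Package: protsig
Title: Proteomic Stratification and Discriminating-Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for stratifying tumour and cell-line cohorts
    from label-free proteomics data. Implements MaxLFQ-style protein
    quantification from peptide intensities (median pairwise ratios with
    least-squares profile reconstruction), MaxQuant-style protein-group
    filtering, left-censored (down-shifted normal) missing-value imputation,
    protein variability profiling, Spearman-distance hierarchical clustering
    and PCA, SAM-type s0-moderated test statistics with permutation-based
    false-discovery control, Fisher's-exact and rank-based one-dimensional
    annotation enrichment, SVM one-versus-all feature selection under
    cross-validation resampling for discriminating-signature assembly,
    signature application to external cohorts, and Kaplan-Meier survival
    comparison of the resulting clusters. Includes a synthetic-data generator
    with planted group structure for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
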