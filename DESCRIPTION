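Package: telostrat
Title: Telomerase-Activity Stratification and Senescence Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratifies tumor samples into low and high telomerase-activity
    groups by consensus k-means clustering of per-sample activity scores,
    scores gene signatures (such as a 125-gene senescence program) with
    single-sample enrichment engines for bulk (ssGSEA-style running sum),
    single-cell (rank/odds-ratio composite), and spot-level (recovery-curve
    AUC) expression data, and links the groups to clinical, genomic-instability
    and pathway features through an association battery (Fisher's exact test,
    Welch t with Cohen's d, Wilcoxon rank-sum with Hodges-Lehmann shift,
    Spearman correlation, Benjamini-Hochberg FDR). A seeded synthetic-cohort
    generator plants the assumed statistical structure (activity-score mixture,
    anti-correlated senescence program, group-elevated mutation burden and
    copy-number features, covariate odds ratios, cycling and non-cycling
    single cells) so every stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea
Config/testthat/edition: 3
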