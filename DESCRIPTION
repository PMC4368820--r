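Package: hta
Title: Heterogeneity-Aware Differential Expression Testing and Method
    Reliability Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential expression testing for two-cohort expression
    contrasts that respects molecular heterogeneity.  Samplewise technical
    error variances are estimated from pairwise array comparisons within a
    cohort, propagated through precision-weighted cohort means, and used in
    a z-test with Benjamini-Hochberg false discovery rate control.  Also
    provides reference methods (pooled two-sample t-test and the hybrid
    p-value plus fold-change selection), Fisher exact gene-set
    overrepresentation, a reliability benchmarking platform scoring
    methods by relative specificity, sensitivity and reproducibility
    across data sets, a progressive permutation-degradation validation,
    and a simulator of genetically identical and molecularly heterogeneous
    sample cohorts with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
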