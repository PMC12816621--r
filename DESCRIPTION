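Package: glycostrat
Title: Glycolysis-Based Stratification of Pancreatic Ductal Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Glycolytic gene-signature scoring and patient stratification for
    pancreatic ductal adenocarcinoma (PDAC) transcriptomes, bulk and
    single-cell. Provides median and tertile stratification of cohorts by a
    14-gene glycolytic score, a permutation test of interpatient
    heterogeneity based on mean pairwise embedding-centroid distances,
    hypoxia-signature construction by gene-set intersection, basal-like versus
    classical molecular subtype calling, contingency-table association testing
    with Benjamini-Hochberg adjustment, 3-year overall-survival endpoints
    (Kaplan-Meier, log-rank, trend test), a spatial-profiling ROI quality
    filter, and synthetic single-cell and cohort simulators so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
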