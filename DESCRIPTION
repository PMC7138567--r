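Package: preservenet
Title: Module Preservation and Hub Significance in Weighted Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks per cohort
    (soft-thresholded adjacency, topological overlap), detects modules by
    dynamic hybrid tree cutting with eigengene merging and a k-means
    refinement step, tests module preservation between cohorts with a
    permutation test on seven preservation statistics, scores hub genes in
    non-preserved modules by five centrality metrics with a
    label-permutation significance test, and provides local
    over-representation, GWAS-enrichment and SNP/miRNA join statistics.
    Includes a synthetic two-cohort data generator with planted module,
    hub and preservation ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
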