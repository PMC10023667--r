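Package: ctpls
Title: Consensus Cortical-Thickness-Associated Gene Discovery with PLS
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers consensus genes whose regional expression tracks
    MRI-derived cortical thickness (CT) across age groups, following the
    imaging-transcriptomics workflow used for regional brain expression
    atlases: sample-level sequencing quality control, expressed-gene and
    low-expression filtering, region aggregation, single-component partial
    least squares (PLS1) regression of CT on regional expression with
    permutation tests of explained variance and bootstrap Z-scores of gene
    weights, per-age gene selection, persistence intersection across ages,
    a Pearson-correlation/FDR filter, and Fisher-exact enrichment of the
    resulting PLS1+/PLS1- gene lists against cell-type marker sets and
    functional gene panels.  A synthetic-data module plants CT-associated
    genes, QC outliers, and enriched marker sets with known ground truth so
    the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
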