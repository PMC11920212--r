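Package: perturbatlas
Title: Genotype Assignment, Cell-State and Heterogeneity Analysis for Yeast Perturb-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale yeast Perturb-seq screens built on
    RNA-barcoded knockout collections. Calls genotype and clone identity per
    cell from targeted amplicon reads with mismatch-tolerant anchor matching
    and a majority-vote rule, merges amplicon and expression-matrix calls,
    performs QC, normalization, cell-cycle scoring, graph-based cell-state
    clustering, marker discovery and independent-filtering differential
    expression, tests genotype-by-state enrichment with Fisher exact tests,
    quantifies per-cell transcriptional heterogeneity with SVD leverage
    scores scaled to wild type, classifies core versus responsive states
    across conditions by label transfer, and runs permutation tests of
    fitness for genotype sets. Includes a synthetic-data generator emulating
    the barcode cassette, targeted amplicon reads and structured
    gamma-Poisson count matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    methods,
    irlba,
    RANN,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
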