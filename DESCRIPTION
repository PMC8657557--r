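Package: methylRescue
Title: Differential Methylation Rescue Analysis for Partial-EMT Cell Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Illumina EPIC-style DNA methylation array
    experiments contrasting demethylating-drug treatment against vehicle in a
    four-group cell-line design. Provides probe-level quality control presets
    (detection p-value, bead count and annotation filters), a beta-mixture
    quantile (BMIQ) normalization of type II probe betas onto the type I
    distribution, per-probe equal-variance t-tests with Benjamini-Hochberg
    false discovery rate control, and identification of "rescue" CpG sites
    whose drug-induced demethylation reverts a knockdown-induced gain in
    methylation. Companion tools quantify cell-morphology roundness with
    control-derived epithelial/mesenchymal cutoffs and mask-based functional
    assays (wound closure, spheroid invasion, BrdU fraction). A synthetic-data
    module generates EPIC-like datasets with planted ground truth so every
    stage is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
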