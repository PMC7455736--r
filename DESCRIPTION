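Package: methylTIME
Title: Methylation-Based Deconvolution of the Tumor Immune Microenvironment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reference-based estimation of immune-cell composition in bulk
    tumor DNA methylation profiles. Builds a cell-type signature matrix from
    pure-population reference methylomes by balanced pairwise selection of
    differentially methylated CpGs with post-selection quality-control
    filters, estimates relative cell-class proportions by linear-kernel
    nu-support-vector regression with permutation significance, and provides
    the surrounding analysis layer: in-silico mixture simulation and recovery
    benchmarking, orthogonal validation scores (meTIL, cytolytic score,
    microglia-to-peripheral-monocyte ratio, single-sample gene-set
    enrichment), consensus k-means clustering of immune profiles with
    PAC-based model selection, and group/survival association statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    S4Vectors,
    SummarizedExperiment,
    survival,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    yaml
Config/testthat/edition: 3
biocViews: DNAMethylation, ImmunoOncology, Epigenetics, CellBiology,
    Software
RoxygenNote: 7.3.3
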