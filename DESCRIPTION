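Package: phagoScreen
Title: Analysis of Pooled CRISPRi FACS-Sort Phagocytosis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled CRISPR-interference screens read out by
    fluorescence-activated sorting, as used to assess regulators of
    microglial phagocytosis and synaptic pruning. Covers the full desk
    side of such a screen: sgRNA library handling, read-to-protospacer
    counting, guide- and gene-level enrichment statistics with
    non-targeting-control pseudogenes and an empirical false discovery
    rate, and a generative simulator (Poisson infection, quartile
    sorting, Dirichlet-multinomial sequencing) with known ground truth.
    Companion quantifications from the same experimental programme are
    included: perturbation-level transcriptomic cluster occupancy,
    time-lapse surveillance-area and colocalization metrics, and
    flow-cytometry uptake readouts with in-well paired comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    EBImage,
    mclust,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
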