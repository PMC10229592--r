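Package: obsight
Title: Observability-Based Biomarker Discovery from Transcriptome Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models perturbation-induced transcriptome fold-change dynamics
    with exact dynamic mode decomposition (DMD), ranks genes by their
    contribution to the observability of the learned linear system via a
    Gram-matrix sensor-placement optimization, reconstructs the cell state
    from small gene subsets with the Moore-Penrose pseudoinverse, selects
    low-correlation high-reconstruction biomarker gene sets, and
    characterizes fluorescent reporter dose-response with Hill transfer
    curves. Includes a synthetic-data generator emulating two-condition
    time-series RNA-seq with planted perturbation-responsive genes, and an
    end-to-end pipeline with seeded, reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
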