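Package: SynergyDE
Title: Detection of Synergistic Gene-Expression Regulation After Combined
    Receptor Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Consensus differential expression under a blocked factorial
    design, qualitative synergy via exclusive set-intersection (UpSet)
    classification of DEG lists, quantitative synergy via a symmetric
    fold-change additivity null model with a paired test, gene-set
    over-representation analysis with a random-set calibrated significance
    threshold, and the computational parts of phenotype assays
    (density-crossing senescence thresholding, 2^-ddCt relative
    quantification, paired nonparametric tests). Includes a synthetic-data
    generator emulating paired multi-arm receptor-activation RNA-seq
    experiments so the full pipeline can be exercised and validated without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    DESeq2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
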