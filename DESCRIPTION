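Package: gcdecay
Title: GC-Content-Dependent mRNA Stability and Translation Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis cascade for multimodal mRNA regulation measured by
    paired RNA-seq and Ribo-seq along a protein-depletion time course:
    negative-binomial GLM likelihood-ratio tests for translation-efficiency
    changes with assay-type interaction covariates, transcript feature
    engineering centred on coding-sequence GC content, Random Forest and
    Lasso feature-importance modelling, SLAM-seq T>C conversion stability
    tests, and a 5'-end coverage-decay statistic. Ships a synthetic-data
    generator with planted GC-dependent stabilization so every stage is
    testable end-to-end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    glmnet,
    randomForest,
    yaml,
    jsonlite,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
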