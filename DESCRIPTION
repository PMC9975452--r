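Package: cffeatures
Title: Whole-Genome Cell-Free DNA Fragmentomics Features and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts whole-genome fragmentomic features from aligned
    plasma cell-free DNA fragments: fragment-size quality control with a
    hemolysis risk flag, short-to-long fragment-size ratio and fragment
    fraction profiles in large genomic bins with GC correction, bin-level
    copy-number scores against a healthy reference panel with gene-level
    amplification calls, transcription start site relative coverage and
    chromatin-state calls, promoter fragmentation entropy, and composite
    nucleosome-occupancy profiles around transcription-factor binding
    sites. The per-sample features feed a cross-validated
    cancer-versus-healthy classifier trained by stochastic gradient
    descent. A seeded synthetic fragment simulator with ground-truth
    tables makes every stage testable without patient data, and a
    config-driven pipeline runs all stages reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    Rsamtools,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    randomForest,
    e1071,
    optparse
Config/testthat/edition: 3
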