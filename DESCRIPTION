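Package: tepop
Title: Population Genomics of Polymorphic Transposable Element Insertions
Version: 0.1.0
Authors@R: person("tepop", "maintainers", email = "tepop@example.org", role = c("aut", "cre"))
Description: Windowed population-genetic statistics (nucleotide diversity,
    Watterson's theta, Tajima's D, Hudson and Weir-Cockerham Fst, reduction of
    diversity) and a three-stage empirical-outlier scan for adaptive
    transposable-element (TE) insertions, together with 24-nt siRNA locus
    construction and TE labelling, TE genic-landscape classification,
    TE insertion-frequency and purifying-selection analysis, and TE-proximity
    gene-expression analysis. A coalescent-style synthetic-data module
    generates every input the pipeline consumes, with known planted truth, so
    each stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
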