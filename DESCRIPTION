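Package: paleoprog
Title: Pseudotime-Informed NMF Expression Programs and Paleogenomic
    Regulatory Islands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two computational engines for studying gene regulation during
    human corticogenesis. A pseudotime-informed non-negative matrix
    factorization (piNMF) constrains temporal expression patterns to
    non-negative spline functions of pseudotime, solved by hierarchical
    alternating least squares, with consensus recovery of stable gene
    expression programs across random-restart replicates and
    regression-based assignment of genes to (semi)discrete modules. A
    paleogenomic pipeline builds an open-chromatin peak atlas, calls
    "regulatory islands" (windows of at least 3 kb around high-frequency
    Homo sapiens-derived variants at which archaic hominins carry the
    ancestral allele and acquired no lineage-specific derived changes),
    links them to genes through GREAT-style regulatory domains, tests
    enrichment against target region sets by permutation, and scores
    allele-specific transcription-factor binding-affinity changes with an
    information-content position weight matrix method. A synthetic-data
    module generates ground-truthed bifurcating trajectories and toy
    regulatory landscapes for benchmarking both engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
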