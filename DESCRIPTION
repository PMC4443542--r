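Package: domarch
Title: Domain-Arrangement Similarity Measures and Orthology Search-Space Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuous similarity measures between protein domain arrangements
    (cosine and maximal-weight matching over a sparse domain-domain similarity
    matrix, at order 1 on single domains or order 2 on consecutive domain pairs,
    with an optional weighting scheme), tandem-repeat collapsing, k-medoids
    pre-clustering of unique domain arrangements into orthology search
    sub-spaces, a pluggable orthology backend with a built-in reciprocal
    best-hit toy engine, merging of per-sub-space results into a single
    orthology table, and evaluation machinery: five-category comparison of
    predicted against reference ortholog groups and ROC/AUC benchmarking of the
    similarity measures on labelled protein families. Seeded synthetic
    generators (block-structured similarity matrices, domain-annotated protein
    families, toy amino-acid sequences) make every step testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats
Suggests:
    cluster,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
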