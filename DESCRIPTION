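Package: mllscape
Title: Interaction Scoring and Functional Annotation of MLL-Fusion
    Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring bait-specific protein interactions from
    multi-channel affinity-purification mass spectrometry (AP-MS) data with
    a Bayesian Poisson/log-normal generalized linear model, combining
    per-channel evidence by Fisher's method, and applying a top-k plus
    cross-bait conservation filter to define a conserved interactome.
    Downstream helpers build the known-interaction network, detect
    communities by modularity maximization, and test complex/annotation
    enrichment. Companion modules score competitive-proliferation shRNA
    screens against control anchors, aggregate published essentiality
    calls, and classify genes by a dual histone-mark (H3K36me3/H3K79me2)
    signature from spike-in normalized ChIP counts. Ground-truthed
    synthetic-data generators emulate each input so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    fgsea,
    jsonlite,
    readr,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
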