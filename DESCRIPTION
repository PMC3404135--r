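Package: quorumotif
Title: Exact Quorum Planted (l,d)-Motif Search and Binding-Site Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact branch-and-bound search for quorum planted (l,d)-motifs in
    DNA and protein sequences: the single-pivot mutation-tree algorithms
    qPMSPrune and qPMSPruneI (surviving-window lists), the two-pivot
    algorithm qPMS7 built on Hamming-ball intersection feasibility, and a
    brute-force enumeration oracle, together with a planted-instance
    simulator for benchmark-style datasets and a two-phase transcription
    factor binding site discovery framework that ranks candidate motifs by
    sequence specificity under an i.i.d. background model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    optparse,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
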