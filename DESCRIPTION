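Package: microsearch
Title: Phylogeny-Aware Similarity Search for 16S rRNA Community Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact similarity search of 16S rRNA microbial community profiles
    against a sample database using a sparse Earth-Mover-Distance formulation
    of weighted UniFrac. Provides metric-space indexes (geometric near-neighbor
    access trees and the approximating-and-eliminating search algorithm) with
    recorded distance evaluations, context selection and distance-matrix
    composition for ordination (PCoA) and average-linkage clustering, empirical
    p-values from binned database distance histograms, a coarse Bray-Curtis
    search against clustering-derived representatives, pairwise adaptive
    rarefaction and 16S copy-number correction, and a synthetic-fixture
    generator producing ecosystem-structured sparse abundance profiles on
    random phylogenies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    biomformat,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
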