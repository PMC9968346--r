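Package: sievescape
Title: Reconstructing Adaptive Responses to Post-Glacial Range Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the interplay of range expansion and
    adaptation since the Last Glacial Maximum from population genomic and
    environmental data. Implements the directionality index psi from
    two-population site frequency spectra with time-difference-of-arrival
    (TDOA) inference of the expansion origin, ensemble species distribution
    modelling with dispersal-limited forward colonisation from glacial
    refugia, gradient-forest style gene-environment turnover functions, the
    glacial genomic offset metric linking present-day populations to their
    refugial sources, and its validation against site-frequency-spectrum
    diversity and neutrality statistics (Tajima's D, Fu and Li's F, Fay and
    Wu's H, Zeng's E). A synthetic landscape, expansion and allele-frequency
    generator with known ground truth supports end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    geosphere,
    igraph,
    glmnet,
    mgcv,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    rpart,
    vcfR,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
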