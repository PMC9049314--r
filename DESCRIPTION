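Package: vafevo
Title: Synthetic Supervised Inference of Subclonal Selection from Tumour
    Variant Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@vafevo.org", role = c("aut", "cre"))
Description: Infers ongoing subclonal selection in bulk-sequenced single
    tumour biopsies from the variant allele frequency (VAF) distribution of
    diploid heterozygous point mutations. Provides paired stochastic and
    generative simulators of tumour evolution (a rejection-kinetic branching
    process with stochastic driver arrival and multiplicative fitness, and a
    Pareto neutral-tail sampler), a virtual biopsy sequencing-noise model
    (binomial depth, beta-binomial reads, purity dilution), depth-conditioned
    VAF histogram featurization with tumour-adapted Tajima's D and Fay & Wu's
    H statistics, a multi-task one-dimensional convolutional network trained
    on the simulations with Monte Carlo dropout uncertainty, parsimony-based
    evolutionary calls, purity correction and clonal-peak adjustment,
    heuristic subclone clustering, evolutionary-parameter rescaling, and a
    transfer-learning pipeline for inferring mutation rate, subclone fitness,
    emergence time, and cellular fraction from a deterministic-subclone
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    stats,
    utils,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
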