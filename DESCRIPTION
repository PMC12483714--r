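Package: rcbtl
Title: Bayesian Rank-Clustered Bradley-Terry-Luce Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian inference for overall rankings with rank-clusters (ties in
    population-level rank) from ordinal comparison data. Fits Bradley-Terry-Luce
    (Plackett-Luce) models in which groups of objects may share exactly equal worth,
    via a partition-based spike-and-slab fusion prior on the worth parameters.
    Estimation uses a reversible-jump Gibbs sampler that alternates birth/death
    moves on the partition of objects with closed-form Gamma updates of cluster
    worths after latent exponential data augmentation. Handles complete, partial,
    incomplete, pairwise, and groupwise comparison data, and provides synthetic
    data generators, posterior co-clustering summaries, credible intervals for the
    number of rank-clusters, and posterior predictive goodness-of-fit checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
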