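Package: operonevo
Title: Stochastic Models for the Evolution of Bacterial Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulators for studying how clusters of functionally related
    genes arise and persist on circular bacterial chromosomes. Implements
    three stochastic models on a shared genome representation: a selfish
    operon species-pool simulation in which horizontal transfer is biased
    towards compact gene arrangements, a Moran process with genome
    inversions under direct selection for gene proximity, and a
    rearrangement-substitution (origin-fixation) model using
    diffusion-theory fixation probabilities and times. Includes latin
    hypercube parameter exploration with Kendall rank-correlation
    summaries, a plain-text configuration loader, and TSV/JSON run
    serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
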