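Package: SeqVAE
Title: Variational Autoencoders for Ancestral-Like Protein Sequence Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trains a small variational autoencoder (VAE) on a query-anchored
    protein family multiple sequence alignment, verifies its generative
    capacity (first- and second-order site statistics, reconstruction-accuracy
    control sets) and the phylogenetic geometry of its two-dimensional latent
    space (depth-origin correlation, branch directionality), and generates
    candidate ancestor-like sequences by decoding equally spaced points on the
    straight line from the query embedding to the latent-space origin, each
    annotated with a statistical design profile. Supports conditional VAEs
    with discretized solubility tags, and ships a phylogeny/MSA simulator
    with planted covariation and planted solubility so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    ape,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
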