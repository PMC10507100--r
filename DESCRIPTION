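Package: phiconet
Title: Compositional Phi-Proportionality Networks for Amplicon Sequence Variant Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of multi-group amplicon sequence variant (SV)
    count tables from soil communities under crop rotation: rarefaction and
    Shannon alpha-diversity with Tukey-Kramer pairwise tests, Bray-Curtis
    beta-diversity with NMDS ordination and PERMANOVA, Monte-Carlo centered
    log-ratio transformation with Dirichlet instances, pairwise
    phi-proportionality and thresholded co-occurrence networks per sample
    group, classification of node SVs into core, common, and crop- or
    field-specific sets across group networks, soil-chemistry normalization
    and clustering, and redundancy analysis of clr-transformed communities
    against chemistry. Includes a synthetic-community generator with planted
    proportional modules for recovery-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
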