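Package: eflratchet
Title: Elongation-Factor Gain/Loss Ratchet and Differential Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the distribution and sequence divergence of the
    eukaryotic translation elongation factors eEF1A, its guanine nucleotide
    exchange factor eEF1Balpha, and the eEF1A-like paralog EFL. Provides exact
    association tests between EFL presence and eEF1A/eEF1Balpha loss from
    three-state (present/divergent/absent) phylogenetic profiles, tiered
    consensus calling and differential-conservation site classification for
    paired protein alignments (including conserved insertion/deletion detection
    and alignment-to-residue coordinate mapping), a continuous-time Markov
    model of gene gain and loss on phylogenies with lethal-state constraints
    (the evolutionary ratchet), stochastic simulation, master-equation
    propagation, pruning likelihoods and rate inference, and seeded synthetic
    data generators for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
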