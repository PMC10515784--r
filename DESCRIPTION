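Package: epbdr
Title: DNA Breathing Dynamics Under the Extended Peyrard-Bishop-Dauxois Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-resolved simulation of spontaneous DNA strand-separation
    ("breathing") dynamics with the mesoscopic Extended Peyrard-Bishop-Dauxois
    (EPBD) lattice model: Morse on-site potentials per base pair, sequence-
    dependent anharmonic stacking, and Metropolis Monte Carlo sampling of the
    transverse base-pair displacements. Computes the standard breathing
    characteristics (average opening profile, base-flipping probability,
    bubble-probability tensor over start position, length and amplitude
    threshold) and the dynamic length -- the FDR-controlled count of base pairs
    whose breathing differs significantly between two alleles. Includes exact
    quadrature oracles for one- and two-base-pair systems used to validate the
    sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
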