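Package: rnatopo
Title: Topological Constraints on RNA Tertiary Folding from Coarse-Grained
    Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-bead coarse-grained model of RNA with fixed secondary
    structure that isolates the steric and chain-connectivity ("topological")
    constraints helices impose on tertiary folding. Secondary structures
    (including pseudoknots) are parsed into helix/linker topology graphs,
    mapped onto rigid A-form duplexes joined by freely rotatable chains, and
    sampled with Metropolis Monte Carlo under temperature replica exchange.
    The analysis stack computes interhelical Euler angles and the fraction of
    discretized orientation space sampled, normalized mutual information
    between helix orientation distributions, contact probabilities, and the
    conformational free energies derived from them: contact penalties
    (dG_topo), tertiary cooperativities (ddG_coop), and reference-transferred
    folding free energies (dG_fold) for tetraloop/receptor interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    bio3d,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
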