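Package: pepconf
Title: Conformational and Energetic Analysis of Blocked Tripeptide Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of molecular-dynamics ensembles of capped tripeptides:
    Ramachandran free-energy surfaces by Boltzmann inversion of dihedral
    histograms, nine-region conformational classification with population
    ratios, free-energy minima location on a coarsened periodic grid,
    side-chain orientation (theta-angle) maps, AMBER-style single-point
    energies with a Generalized Born implicit solvent and a
    backbone/side-chain electrostatic decomposition, and discrete
    protonation-state population analysis.  A synthetic-trajectory module
    (von Mises mixtures, Markov protonation switching, idealized toy
    peptides) provides reproducible inputs with the statistical structure
    the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
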