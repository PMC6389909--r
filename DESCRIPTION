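Package: isoDSF
Title: Isothermal Analysis of Differential Scanning Fluorimetry Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts quantitative protein-ligand dissociation constants from
    differential scanning fluorimetry (DSF / ThermoFluor / thermal shift)
    melt curves. Individual unfolding curves collected across a ligand
    dilution series are fit with either an empirical Boltzmann sigmoid or a
    two-state thermodynamic model (Gibbs-Helmholtz with fixed heat-capacity
    change), optionally with globally shared dye-baseline slopes. The fitted
    curves are then sliced at a single temperature near the melting
    transition, and the resulting fraction-unfolded versus total-ligand data
    are fit with a coupled folding/binding equilibrium model to yield the
    dissociation constant K_d and the ligand-free unfolding constant K_U at
    that temperature, together with closed-form EC50 to K_d conversions. A
    thermodynamic simulator generates realistic melt-curve families from
    unfolding and binding parameters for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
biocViews: Proteomics, Cheminformatics, Regression
RoxygenNote: 7.3.3
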