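Package: pasorption
Title: Langmuir Modelling of Proanthocyanidin Adsorption and Desorption on
    Grape Cell Wall Material
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for modelling the reversible adsorption of grape
    proanthocyanidins (condensed tannins) onto skin-derived cell wall
    material in model wine. Implements temperature- and ethanol-dependent
    rational surfaces for the Langmuir equilibrium constant and saturation
    capacity, a closed-system batch equilibrium solver, isotherm fitting,
    simulation of sequential temperature-ramp desorption experiments, the
    ferric chloride assay quantification chain, desorption summary
    statistics with compact letter displays, proanthocyanidin compositional
    calculators (mean degree of polymerization, percent galloylation,
    percent gallo units, average molecular weight, GPC cumulative molar
    mass quantiles), a winemaking extrapolation comparing model-predicted
    and cold-soak tannin losses, and a seeded synthetic-data generator that
    emulates the triplicate bench experiment.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    multcomp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
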