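Package: tetra
Title: Integrative Hybrid Analysis of the Coagulation Factor XIII Heterotetramer
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computational core of an integrative-hybrid structural study of the
    plasma coagulation factor XIII A2B2 heterotetramer. Converts chemical
    cross-link residue pairs into distance restraints (3-24 Angstrom DSS
    bounds), scores their satisfaction on atomic models and summarizes
    interfaces by domain pairs; simulates atomic-force-microscopy height
    topographs by hard-sphere tip dilation and rigidly docks atomic models into
    topographs with a favorable-layer score; forward-simulates and fits
    stepwise (sequential binding-site) isothermal titration calorimetry
    models for complex assembly and calcium-driven disassembly, with full
    thermodynamic decomposition into dG, dH and -TdS. Synthetic-data
    generators provide test fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
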