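Package: pharmscreen
Title: Selectivity-Aware 3D Pharmacophore Screening and Ligand-Binding
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for tolerance-sphere 3D pharmacophore screening of posed
    small-molecule conformer libraries, built around a seven-query
    Dishevelled-1 (DVL1) PDZ selectivity model: feature perception
    (aromatic rings, hydrogen-bond donors and acceptors, hydrophobic
    patches), injective query-feature matching with a must-have query and a
    minimum-match rule, Kabsch rigid-body superposition, multi-conformer
    ranking, and shortlist extraction.  Companion quantitative pharmacology
    covers hyperbolic saturation binding (Kd), competitive-shift Kd/Ki
    algebra, four-parameter logistic dose-response (EC50) fitting, and
    growth-inhibition rates.  A seeded synthetic-data generator produces
    planted-truth screening libraries, FRET saturation curves, and
    dose-response series so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    jsonlite,
    minpack.lm,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
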