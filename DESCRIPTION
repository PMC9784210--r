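Package: pefsim
Title: Coupled Electro-Thermal Finite-Element Simulation of Epicardial
    Pulsed-Field Ablation near a Stented Coronary Artery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-dimensional coupled electrical-thermal finite-element
    model of epicardial pulsed electric field (PEF) ablation over the
    epicardial fat layer, with an optional coronary artery and metal
    intracoronary stent beneath the ablation electrode. Solves the
    quasi-static conduction equation with a sigmoid field- and
    temperature-dependent electrical conductivity, advances the bioheat
    equation with Joule heating over a pulse train, and computes lesion
    metrics: the 1000 V/cm PEF-zone isoline and its dimensions, artery
    lumen field statistics, hot-spot temperatures and thermal latency
    behaviour. Includes a deterministic block-structured mesher, a
    scenario factory for the study matrix and analytic benchmark
    fixtures, VTK/CSV/JSON writers and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
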