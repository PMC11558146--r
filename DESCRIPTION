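Package: molvq
Title: Molecular Learning Vector Quantization Networks from DNA Strand
    Displacement Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains learning vector quantization (LVQ) classifiers whose
    prototype vectors are expressed as DNA strand concentrations, compiles a
    trained model together with one input sample into a mass-action chemical
    reaction network built from DNA strand-displacement primitives (catalytic
    input activation, cooperative-hybridization subtraction annihilation,
    absolute-value summation, a loser-take-all competitive layer, and
    fluorescent reporting), simulates the network deterministically with a
    stiff ODE solver, and reads out the diagnosis from the reporter
    concentrations. Includes synthetic cohort generators, module-level test
    fixtures across three concentration ranges, conservation-law extraction,
    SBML and reaction-list export, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
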