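Package: nephrosim
Title: Sex- and Species-Specific Steady-State Simulation of Nephron
    Water and Solute Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Steady-state epithelial-cell-based simulation of water and
    solute transport along rat and mouse nephrons. Six nephron classes
    (one superficial, five juxtamedullary) coalesce into a shared
    collecting duct; each segment is a tubule lined by epithelial cells
    whose apical, basolateral and paracellular pathways carry water by
    osmosis, ions by Goldman-Hodgkin-Katz electrodiffusion, and solutes
    through cotransporters, exchangers and ATP-driven pumps. The package
    ships a calibrated male-rat baseline parameter set and a delta engine
    that derives the female rat and the male and female mouse models from
    tabulated relative differences in transporter activities, membrane
    permeabilities, tubular dimensions and filtration rates. Simulation
    protocols reproduce baseline delivery profiles, acute saline loading,
    and segment-swap and sex-swap analyses of transporter patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
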