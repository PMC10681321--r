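Package: sproutmech
Title: Coupled Finite-Element / Agent-Based Simulation of Mechano-Regulated
    Sprouting Angiogenesis in Early Bone Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sprouting angiogenesis and stromal cell organisation
    in the healing region of a stabilized mouse osteotomy during the first
    week after surgery. A plane-strain linear-elastic finite element model
    of the mid-longitudinal healing region (cortices, marrow cavity,
    osteotomy gap, periosteal callus) is iteratively coupled to a lattice
    agent-based model of endothelial tip/stalk cells and outer-vascular
    stromal cells. Tip cells migrate under a probabilistic mix of
    persistence, random walk and a principal-strain guidance rule; stromal
    cells migrate by density-biased random walk and, later, durotaxis, and
    both cell types load the matrix as contractile force dipoles. The
    package provides scenario presets (rigid/semirigid fixation surrogates,
    unloading, mechano-response and traction-force knockouts), replicate
    and parameter-sweep drivers, and the vessel/cell morphometrics used to
    compare simulations with histology (vessel length density, 20-degree
    directionality histograms, vessel length and self-loop statistics,
    stromal orientation fractions, and the associated non-parametric
    statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite,
    png,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
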