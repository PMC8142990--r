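Package: qpmsizer
Title: Single-Particle Sizing of Nanoscale Vesicles by Quantitative Phase
    Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative phase
    microscopy (QPM) of immobilized spherical nanoparticles such as
    liposomes. Generates phase-shifted interferogram stacks of synthetic
    particle fields, recovers the spatial phase map by per-pixel least
    squares when the phase shifts are known or by the alternating advanced
    iterative algorithm (AIA) when they are not, removes background phase,
    converts phase to physical height via the optical path length relation,
    and estimates number- or intensity-weighted single-particle size
    distributions for particles below the diffraction limit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    withr,
    igraph,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
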