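Package: epimech
Title: Deformable-Cell Biomechanics of Epithelial Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sub-cellular element simulator for epithelial tissue mechanics.
    Cells are closed triangulated membranes of particles plus a single
    intracellular particle, coupled by non-linear Morse springs and advanced
    with overdamped first-order dynamics.  Programmed single-cell behaviours
    (elongation, apical constriction, repulsion-driven lumenogenesis) drive
    tissue-level morphogenesis.  Includes builders for a rosette-shaped
    epiblast covered by a trophectoderm cap, scenario scheduling for mouse
    peri-implantation experiments, slice-based shape metrics, an in-silico
    stress-strain protocol for single-cell stiffness estimation, and
    parameter sweeps with a normalised fitness metric.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
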