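Package: memdock
Title: Quantitative Analysis of Membrane Docking Interfaces and Bilayer Relaxation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying membrane-membrane docking interfaces from
    cryo-electron-microscopy-style images and from lipid bilayer particle
    trajectories. Measures bilayer thickness as the distance between headgroup
    intensity peaks in line or radial profiles, classifies vesicle docking
    interfaces as loose or tight from protein-signal depletion, computes
    per-frame membrane observables (P-layer thickness, inter-membrane distance,
    lateral area, volume, headgroup tilt, chain order, gap hydration, and
    leaflet-internal electrostatic energy), fits exponential relaxations to
    replica ensembles to order the time constants of headgroup tilt, area
    shrinkage and membrane thickening, and provides the angle-restraint bias
    potential used to enforce headgroup tilt. A seeded synthetic-data module
    generates ground-truth-annotated vesicle images, bilayer frames and
    relaxation ensembles so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
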