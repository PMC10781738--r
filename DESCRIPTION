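Package: cryofit
Title: Gaussian-Mixture Refinement of Atomic Models Against Cryo-EM Density
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Represents an atomic model as a per-atom Gaussian mixture with a
    uniform background component and refines atomic positions and per-atom
    B-factors (Gaussian widths) against a cryo-EM density map by
    expectation-maximisation. From the refined widths it generates model
    ensembles and ensemble-average maps, blends pre-aligned focused maps into
    seam-free composites via component responsibilities, and computes local
    quality-of-fit scores (local-FSC LoQFit and windowed Manders overlap).
    Includes MRC2014 map input/output, PDB/mmCIF model input/output and a
    synthetic fixture generator so that every step can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
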