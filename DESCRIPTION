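Package: durotaxr
Title: Quantification of Tissue Stiffness Gradients and Durotactic Cell
    Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying durotaxis, the migration of cells up
    gradients of substrate stiffness. Fits atomic force microscopy (AFM)
    force-indentation curves with the Hertz spherical-contact model,
    assembles gridded stiffness maps (elastographs) and summarises their
    spatial gradients with a transect slope statistic and peak/valley
    detection. Models mechanically patterned hydrogel substrates
    (striped step gradients, continuous shallow gradients, soft islands),
    computes end-point durotactic indices and time-lapse migration
    statistics (path length, speed, straightness, forward migration
    index, rose histograms, drift correction), and derives tumour
    dissemination metrics (bioluminescence metastatic index, collagen
    fibre geometry). Seeded synthetic-data generators emulate every
    input - Hertzian force curves, healthy and fibrotic stiffness
    fields, persistent biased random walks, photon-flux tables and
    fibre centerlines - so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
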