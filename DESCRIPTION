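Package: biofilmq
Title: Quantification of Biofilm Architecture from Multi-Channel Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional architecture of
    concrete-pipe biofilms imaged by multi-channel confocal laser scanning
    microscopy. Reads multi-channel z-stacks, applies shadow (illumination)
    correction, segments extracellular polymeric substance (EPS) components
    (protein, polysaccharide, nucleic acid, lipid) and bacterial channels by
    thresholding, extracts per-component fluorescent volumes, estimates
    component and total EPS masses from a measured biofilm mass,
    computes depth-resolved composition profiles with k-means layer
    clustering, performs representative elementary volume (REV) analysis,
    exports iso-surface meshes, and detects and classifies protein-like peaks
    in three-dimensional excitation-emission matrices (3D-EEM). A seeded
    synthetic-data generator produces ground-truthed stacks and EEM grids so
    that every pipeline stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
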