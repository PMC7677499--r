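Package: spaceball
Title: Grid-Based Detection and Characterization of Cavities in Biomolecular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-grid detection of internal cavities in protein structures using a
    solvent-probe "rain" cast from the six walls of a bounding box, with
    connected-component chamber labeling, rotation-averaged cavity and total volumes,
    grid-native cavity surface areas and the closure fraction used to separate pockets
    from true cavities, and chemical and shape descriptors of the cavity shell
    (Kyte-Doolittle hydropathy sum and vector, radius of gyration, inertia-tensor
    shape parameter). Includes generators for synthetic PDB-format test structures
    with analytically known cavity properties, and a batch survey mode with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
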