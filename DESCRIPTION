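Package: porepose
Title: Pose-Ensemble Analysis for Ion-Channel Pore Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of ligand docking pose ensembles in homotetrameric
    ion-channel pores. Provides ranked pose selection from Rosetta-style score
    tables, a rotation-invariant pose descriptor triple (axial position, end-to-end
    length, polar tilt) with range-normalised pairwise dissimilarities, two-stage
    clustering (cutoff/minimum-size leader clustering refined by seeded K-means),
    geometric pore-region classification with hydrophobic-pocket and enclosure
    occupancy statistics, pore-radius profiling along the channel axis, and
    simplified geometric protein-ligand interaction fingerprints. A synthetic
    C4-symmetric channel scaffold and pose-ensemble generator with planted ground
    truth supports end-to-end testing without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
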