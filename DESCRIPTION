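Package: chanflux
Title: Water Transport Analysis for Channel-Protein Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for water transport through membrane channel
    proteins (aquaporins and relatives) from molecular dynamics trajectories:
    counting of complete water permeation events, osmotic permeability by the
    collective-diffusion method (pf = vw * Dn), potential-of-mean-force
    profiles from axial water occupancy by Boltzmann inversion, temporal
    pore-radius profiles by maximal inscribed sphere, monomer-monomer
    interface contact maps with difference maps, essential dynamics
    (trajectory principal component analysis), Mann-Whitney U group
    comparison, and global pairwise sequence alignment of channel paralogs.
    Includes seeded synthetic-trajectory generators with ground-truth records
    so every stage is verifiable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
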