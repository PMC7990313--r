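Package: ecdyn
Title: Essential Collective Dynamics and Aggregation Analysis of Peptide
    Simulation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of
    self-assembling peptide mixtures, built around the systems studied in
    amyloid-beta (Abeta40/Abeta42) aggregation with small cyclic
    neuropeptides (somatostatin-14, arginine vasopressin). Provides a
    topology/trajectory data model with PDB/GRO/DCD/XTC readers, geometric
    hydrogen-bond censuses classified by chain species, Kabsch-Sander
    secondary-structure assignment and occupancy statistics, Shrake-Rupley
    solvent-accessible surface area with hydrophobic/hydrophilic splits,
    chain-level contact graphs and aggregate composition timelines, and the
    Essential Collective Dynamics (ECD) descriptors: segment-wise covariance
    PCA, atom images in essential-coordinate space, pair-correlation maps,
    main-chain flexibility profiles and domains of correlated motion. A
    synthetic-trajectory generator with scripted aggregation schedules and
    latent correlated modes supplies ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
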