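Package: rodmap
Title: Quantitative Subcellular Organization Analysis for Rod-Shaped Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies subcellular organization in fluorescence microscopy of
    rod-shaped bacteria such as cyanobacteria. Provides drift correction by
    cross-correlation registration, cell segmentation post-processing and
    midline-based morphology, Laplacian-of-Gaussian focus detection with
    circular intensity integration, linear-assignment particle tracking with
    gap closing and confinement-radius statistics, nucleoid segmentation by
    rim-background fitting and Yen thresholding with a compaction score,
    per-cell normalized-intensity oscillation scoring and kymographs, a
    normalized three-coordinate (radial, longitudinal, polar-angle) cell frame
    with fourfold-symmetrized localization probability-density maps, per-cell
    and per-field Pearson colocalization, ROUT outlier removal with replicate
    summaries, and a synthetic microscopy-scene generator that supplies ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    EBImage,
    tiff,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
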