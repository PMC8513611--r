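Package: colonyquant
Title: Quantitative Image Analysis of Micropatterned Stem-Cell Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for fluorescence images of geometrically
    confined ("micropatterned") human pluripotent stem-cell colonies that
    self-organize into concentric germ-layer domains (2D gastruloids). Covers
    tile stitching and background correction, colony detection and quality
    filtering, seeded-watershed nuclear segmentation, per-cell median marker
    intensities with DAPI normalization, two-Gaussian/Otsu positive-cell
    calling, radial signaling profiles and ring-width estimation, three-region
    germ-layer domain segmentation and area change statistics, apical-surface
    interpolation from ZO-1 z-stacks with signed distance-to-apical readouts,
    live-reporter radius and nuclear-to-cytoplasmic ratio dynamics, and small
    derived assays (TEER per unit area, delta-delta-Ct fold change). Includes
    a synthetic-scene generator with exported ground truth for every imaging
    geometry the pipeline quantifies, so all stages are testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    mclust,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
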