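Package: canopyr
Title: Canopy Roughness Trait Extraction and Biomass Estimation from UAS
    Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for extracting the plot-level canopy roughness trait
    from colored 3D point clouds of crop canopies, as produced by unmanned
    aerial system (UAS) photogrammetry, and estimating aboveground biomass
    from it. Provides point-cloud input/output (PLY, LAS 1.2, XYZ text),
    statistical and plane-fit outlier filtering, height calibration against
    surveyed reference bars, surface regularization (Delaunay meshing, hole
    repair, Laplacian smoothing, uniform resampling, Poisson-disk thinning),
    radiometric vegetation/soil classification, voxel connected-component
    row segmentation, per-point surface roughness, the plot-level canopy
    roughness statistic, and cross-validated univariate biomass regression
    with standardized-residual plot rejection and per-genotype error
    reporting. A synthetic field generator with full ground truth supports
    testing every stage without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    interp,
    jsonlite,
    pracma,
    purrr,
    RANN,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
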