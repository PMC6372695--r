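Package: neuritegeom
Title: Geometric Morphometry of Neurites from Volumetric Brain Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional geometry of neurites
    and dendritic spines traced from high-resolution volumetric images of
    Golgi-stained brain tissue. Provides a node-and-radius coordinate model
    of tissue constituents with SWC and tabular readers and writers,
    splitting of neurite trees into unbranched segments at ramification
    points, discrete Frenet estimators (Menger circumcircle curvature and
    signed-tetrahedron torsion) on arc-length resampled chains, spine
    morphometry (length, neck and head radii, radius ratio) and spine
    density, a synthetic generator of tortuous neurites, spine populations,
    case cohorts and rasterized tube phantoms with analytically known
    geometry, a gradient-vector-flow based centerline tracer with
    conjugate-gradient model refinement, and case-control summary statistics
    (per-case mean/SD/n tables, relative-frequency histograms,
    Kruskal-Wallis and Welch tests, group ratio contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    mclust
Config/testthat/edition: 3
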