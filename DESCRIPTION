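Package: medusamap
Title: Object-Based Detection of Invasive Medusahead Patches from Very
    High Resolution VNIR Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An object-based image analysis (OBIA) workflow for mapping
    patches of the invasive annual grass medusahead (Elymus caput-medusae)
    in mixed-cover grasslands from 0.15 m visible/near-infrared aerial
    imagery at the stage of late-spring phenological contrast.  Provides a
    seeded synthetic-scene generator emulating a senescent-grass matrix with
    green invader patches and spectrally or texturally confusable
    co-occurring vegetation, plus a simulated transect/plot field survey;
    derived raster layers (NDVI, local Moran's I) and multi-level Otsu
    thresholding; multiresolution region-merging segmentation with a
    local-variance scale scan; per-object spectral and GLCM-entropy texture
    attributes; unsupervised k-means, single-run supervised (KNN, diagonal
    Gaussian Bayes, linear SVM) and knowledge-based hierarchical
    classification; fuzzy thematic accuracy assessment (MAX, RIGHT and
    producer's metrics on 1 m reference squares); and validation of
    classified patch extents against field transect segments by
    patch-length category.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    class,
    e1071,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
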