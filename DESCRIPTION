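Package: osteomorph
Title: Limb-Bone Ecomorphology from Voxel Volumes, Landmarks and Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how locomotor ecology and size shape the
    external form and internal structure of long bones. Computes slice-by-slice
    cross-sectional geometry (area, compactness, principal second moments of
    area) from voxelized bone volumes and derives global compactness, diaphysis
    elongation and cross-sectional shape over the mid-diaphysis; performs
    generalized Procrustes analysis, principal components and phylomorphospace
    projection, Procrustes ANOVA/ANCOVA with residual randomization (with and
    without a phylogenetic transform), Pillai's-trace MANOVA, two-block partial
    least squares, and canonical variate analysis with jackknife
    cross-validation on 3D landmark data; fits univariate phylogenetic
    generalized least squares models with jointly estimated Pagel's lambda,
    compares candidate models by AICc weights, and classifies allometry from
    parametric-bootstrap confidence intervals. A synthetic-data module builds
    voxel bones with closed-form cross-sections and simulates traits and shapes
    on birth-process phylogenies so every stage can be verified against known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
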