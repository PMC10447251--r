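Package: MetaboStrat
Title: Metabolic Profile Stratification of Tissues by Mass Spectrometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for stratifying tissues by ambient mass-spectrometry
    metabolic profiles. Implements profile-spectrum preprocessing
    (interpolation rebinning, l2 normalisation, gradient peak picking,
    top-N peak reduction), unsupervised segmentation of REIMS cohorts and
    mass-spectrometry-imaging datacubes (cosine/correlation t-SNE, k-means
    with cosine or Euclidean dissimilarity, elbow-method model selection,
    burn-region and background detection), pairwise differential-ion
    (volcano) analysis with Benjamini-Hochberg FDR control, compound-database
    annotation with pathway frequency ranking and lipid sum-composition
    curation, and a replicate-aware linear SVM classifier with recursive
    feature refinement evaluated by leave-one-patient-out cross-validation.
    A synthetic-data module generates spectral cohorts, imaging datacubes,
    clinical feature tables and a toy compound database with planted ground
    truth so that every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rtsne,
    e1071,
    xml2,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
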