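Package: ceipr
Title: Computer-Extracted Imaging Phenotypes of Breast Lesions on DCE-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study whether computer-extracted imaging phenotypes (CEIP)
    of breast lesions on dynamic contrast-enhanced MRI can replicate the size and
    BI-RADS descriptors assigned by radiologists (HEIP). Provides a synthetic
    3D phantom cohort generator with simulated multi-reader panels, fuzzy
    c-means lesion segmentation from the enhancement signal, extraction of 24
    radiomic features (size, shape, morphology, and Haralick texture),
    inter-observer agreement statistics (log-ratio coverage probability,
    Krippendorff's alpha, nonparametric bootstrap), HEIP-CEIP association
    testing (Kendall tau-b with permutation p-values, Mann-Whitney U,
    Benjamini-Hochberg correction), and elastic-net replication models assessed
    by nested ten-fold cross-validation with permutation signal tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pracma,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
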