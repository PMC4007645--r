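Package: pmnreporter
Title: Transcriptomic Reporter-Assay Analysis of Plasma Immune Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for transcriptomic reporter assays, in which
    healthy-donor leukocytes (typically neutrophils) are stimulated in vitro
    with patient plasma and their genome-wide transcriptional response is read
    out on bead arrays. Implements the normalization and filtering chain for
    background-subtracted probe intensities (quantile normalization, intensity
    flooring, present-in-at-least-one-sample detection filtering, fold change
    against medium-alone controls, and a combined fold-change/intensity-
    difference differential filter), a PCA-based response-amplitude statistic
    measuring each sample's Euclidean distance from the uninfected-plasma
    centroid, hierarchical clustering of response transcripts, random
    k-nearest-neighbor feature selection with geometric backward elimination
    for deriving a severity marker panel, and SVM/random-forest severity
    prediction with ROC curves and bootstrap AUC confidence intervals. A
    synthetic-data generator emulates the assay's statistical structure with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
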