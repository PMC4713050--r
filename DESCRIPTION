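Package: geltexture
Title: Texture-Based Classification of Protein Spots in 2-DE Gel Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a region of interest on a
    two-dimensional gel electrophoresis (2-DE) image is a protein spot or
    noise, using texture information alone. Provides a synthetic gel-image
    simulator with labelled spot and noise regions, extraction of six
    classical texture feature families (histogram, absolute gradient,
    grey-level co-occurrence matrix, run-length matrix, autoregressive
    model, Haar wavelet energies), a sparse feature-selection multiple
    kernel learning classifier (FSMKL) with kernel and feature importance
    reporting, reference classifiers (naive Bayes, SVM, SVM-RFE, GA and
    PSO wrappers, group-wise MKL), a shared cross-validation harness with
    threshold-free metrics, and the nonparametric model-comparison
    workflow (Friedman with the Iman-Davenport extension, Finner
    step-down post hoc adjustment, Wilcoxon signed-rank tie-break).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
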