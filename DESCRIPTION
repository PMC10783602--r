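Package: slidegroups
Title: Gene-Group Latent Factors from Transcriptomes and Their Prediction
    from Whole-Slide-Image Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses a tumour transcriptome into a small number of binary
    "gene group" latent factors discovered by total-correlation explanation,
    and predicts those factor statuses -- both slide-level and spatially
    resolved -- from whole-slide-image patch graphs using a multi-output
    EdgeConv graph neural network trained with a pairwise hinge ranking loss.
    Includes Delaunay patch-graph construction with distance pruning,
    informative-tissue patch filtering, exemplar-patch motif mining by
    k-medoid clustering, bootstrap AUROC evaluation of downstream clinical
    predictors, and a synthetic cohort generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
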