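Package: threatRSA
Title: Representational Similarity Analysis of Helping Under Threat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates threat-imminence helping experiments (trial schedules,
    help/no-help decisions, shock outcomes, post-scan distress and threat
    ratings, and region-of-interest voxel patterns with planted
    representational geometry) and analyses them with a trial-wise
    representational similarity analysis (RSA) pipeline: neural
    representational dissimilarity matrices (1 - Pearson r), behavioral
    dissimilarity matrices from ratings (Euclidean distance), second-order
    similarity by Kendall's tau, per-region linear models predicting helping
    percentage with Benjamini-Hochberg false discovery rate correction, and a
    paired predominance comparison of threat versus distress coding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    sandwich,
    withr
Config/testthat/edition: 3
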