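Package: knnmdr
Title: Window-Based K-Nearest-Neighbour Multifactor Dimensionality
    Reduction for Epistasis Detection in Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Axel", "Moreau", email = "axel.moreau@example.org",
           role = c("aut", "cre"))
Description: Detects gene-gene interactions in case-control SNP panels by
    replacing the per-genotype-cell majority vote of classic multifactor
    dimensionality reduction (MDR) with a K-nearest-neighbour vote over
    window-based genotype distances (KNN-MDR).  Markers are grouped into
    windows of contiguous SNPs, per-window squared distance matrices are
    pre-computed and combined additively, and candidate window sets are
    ranked by 10-fold cross-validated balanced accuracy.  Significance is
    assessed by phenotype-permutation tests with an adaptive early-stopping
    schedule and Bonferroni family-wise control, including a hierarchical
    stride-subsampling scan for large marker panels.  A simulator generates
    case-control datasets with linkage disequilibrium and interacting causal
    SNPs constrained to have exactly zero marginal effects, and a replicate
    harness computes power, corrected power and false-positive rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
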