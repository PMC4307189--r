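Package: p1crosstalk
Title: Bayesian Differential-Network Prediction of Drug-Resistance Signaling Cross-Talks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers signaling cross-talks that distinguish a drug-resistant cell
    line from its drug-sensitive parent. Gene-gene relationship networks are
    built per condition by thresholding absolute Pearson correlations of
    expression profiles over a seed gene list; the two binary networks are then
    fit jointly with an undirected hierarchical Bayesian p1-model (an
    exponential random graph model with a global density parameter and per-gene
    propensity parameters coupled across conditions through a Wishart-prior
    covariance) by Polya-Gamma augmented Gibbs sampling. Gene pairs are scored
    by the odds ratio of their posterior edge probabilities in the resistant
    versus parental networks and intersected with pathway-membership-defined
    cross-talk candidates around a pathway of interest. Includes the
    expression-profile screens (condition averaging, z-score/max-abs heatmap
    normalization, up-regulated-pair and fold-change-reversal selection), a
    model-faithful synthetic-data generator, and a reproducible end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
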