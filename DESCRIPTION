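Package: songculture
Title: Computational Analysis of Birdsong Phonology, Syntax, and Cultural Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative comparison of learned bird song across
    populations, built around acoustic feature contours (fundamental frequency,
    mean frequency, frequency change, harmonicity). Provides contour input/output
    and syllable segmentation, dynamic time warping dissimilarities between song
    units with length-normalized time weighting, cluster discovery and validation
    (partitioning around medoids with a null-corrected global silhouette index,
    non-metric multidimensional scaling, Gaussian mixtures with component
    merging), first-order Markov syntax statistics with finite-sample entropy
    corrections, permutation tests of population divergence (multiresponse
    permutation procedure, permutation chi-square with Cramer's V, spatial
    medians, neighbor-joining dendrograms), an agent-based simulator of song
    cultural evolution under tunable learning-error rates, and a synthetic song
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    vegan,
    mclust,
    ape,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
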