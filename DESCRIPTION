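Package: popdprime
Title: Task-Engagement Effects on Neural Population Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how task engagement reshapes
    sound coding in auditory cortical populations. From trial-structured
    population spike counts (recorded or synthetic go/no-go tone-in-noise
    sessions), the package computes behavioral and neural d-prime,
    population decoding in a two-dimensional space spanned by the
    signal (class-mean difference) and dominant noise-covariability axes
    (decoding-based dimensionality reduction, dDR), factor-analysis
    decompositions of stimulus-independent spike-count covariance
    (shared low-rank covariance plus private variance), pupil-indexed
    arousal regression, and a four-model multivariate-Gaussian ablation
    that attributes engagement-related decoding changes to gain, private
    variance, or shared covariance. A synthetic-session generator with
    known ground truth makes every stage testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
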