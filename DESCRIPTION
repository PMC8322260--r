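Package: ktrdyn
Title: Single-Cell Dynamics of ERK Signaling Inhibition and Reactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying kinase-translocation-reporter (KTR)
    time-lapse microscopy of BRAF-inhibited melanoma cells and for detecting
    heterogeneous signaling reactivation. Provides a seedable synthetic-data
    generator (two-phase activity traces, rendered two-channel movies, cell
    lineages, in-cell-western plates), nuclei segmentation and cytoplasm-ring
    quantification, drift-corrected nearest-neighbour cell tracking, a
    three-parameter two-phase linear fit of per-cell signaling dynamics,
    Gaussian-mixture bimodality testing with parametric-bootstrap
    Kolmogorov-Smirnov p-values, lineage-size association tests, and
    in-cell-western normalization with Bonferroni-corrected reactivation
    tests. All results are returned as tibbles and compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    tiff,
    EBImage,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
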