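Package: lapscore
Title: Cell-Type Identity Scoring by Orthogonal Projection onto Reference
    Expression Bases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores query transcriptomes against a labeled reference basis of
    cell-type expression profiles using least-squares (dual-basis) projection.
    Heterogeneous platforms (microarray intensities, RNA-Seq counts) are made
    comparable by per-sample rank-quantile normalization to standard-normal
    profiles on a shared gene universe; a high-expression gene filter and a
    pseudoinverse dual operator give projection scores in which each reference
    type scores 1 only with itself; significance is calibrated against a
    random-profile null with a five-standard-deviation threshold. An
    independent single-sample gene-set scoring method (weighted ECDF
    difference) and a synthetic-data generator with known ground truth
    (correlated reference profiles, mixture queries, over-dispersed counts,
    clustered single-cell data with dropout) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
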