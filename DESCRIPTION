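Package: psdg
Title: Partially Synthetic Data Generation and Imputation via 2D Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates and validates partially synthetic values for tabular
    health-record data. An incomplete table missing one feature (and/or its
    class label) is expanded over a finite grid of candidate values, projected
    through a 2D embedding trained on a complete reference table, and each
    candidate is scored by the disparity between its value and the mean of
    that feature over its k nearest reference points in the embedding.
    Candidates passing a reliability threshold form a partially synthetic
    dataset; class labels can be assigned by density-thresholded cluster
    areas around per-class centroids. Includes iterative full synthesis,
    per-pattern imputation, mean and k-NN imputation baselines, a rotation
    evaluation harness, two-party exchange operations, and a synthetic
    fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
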