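Package: crossbear
Title: Cross-Species Imputation and Comparison of Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes single-cell RNA-seq count profiles into
    species-invariant cell factors and species, batch and tissue factors
    using a conditional variational autoencoder with a zero-inflated
    negative binomial likelihood and an optional adversarial species
    discriminator. Swapping the species factor at decoding time imputes a
    cell's expression profile in another species. Also provides greedy
    one-to-one orthology reconciliation with transitive triangle filling,
    barnyard species demultiplexing and count-matrix quality filters,
    pseudobulk evaluation baselines, X-chromosome-upregulation statistics
    (housekeeping normalization, per-gene median log2 fold changes,
    one-sample signed-rank tests, GGACH motif frequencies), and seeded
    synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
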