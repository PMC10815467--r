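Package: igrnet
Title: Intercellular Gene Regulatory Networks from Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and prunes intercellular gene regulatory networks
    (ligand -> receptor -> transcription factor -> target gene) between a
    sender immune population and a receiver malignant population from
    single-cell expression data. Includes cell quality filtering,
    library-size normalization and highly-variable-gene selection,
    expression-derived copy-number profiling with malignancy calling,
    spatial K-distance statistics with invasive-front calling,
    permutation-based ligand-receptor scoring, regulon inference with
    per-cell AUC activity, Wilcoxon differential expression, a deterministic
    synthetic-data generator with planted ground truth, and a config-driven
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
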