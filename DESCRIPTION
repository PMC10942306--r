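Package: chronocell
Title: Multi-Condition and Multi-Modal Temporal Profile Inference for
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint modeling of single-cell time-series profiles across
    conditions and data modalities. A conditional variational autoencoder
    with a zero-inflated negative binomial likelihood decomposes scRNA-seq
    profiles into cell-identity, time, condition and batch factors; an
    adversarial discriminator encourages cell embeddings to be independent
    of time; a Bernoulli-likelihood branch with a shared time layer extends
    the model to binarized scATAC-seq via co-assay-guided stepwise training.
    Trained models impute denoised profiles at unobserved time points, in
    unmeasured conditions and in missing modalities. Downstream tools
    include signed-rank sex-bias scoring, gene-set and protein-interaction
    enrichment statistics, time-lagged cross-correlation between chromatin
    accessibility and expression trajectories, a model-selection and
    evaluation harness, and a seeded multi-omic simulator with planted
    ground truth.
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
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    nnet,
    jsonlite,
    withr
Config/testthat/edition: 3
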