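Package: odorvalence
Title: Valence and Identity Encoding Analyses for Calcium Imaging in
    Odor Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium imaging of neural
    populations during Pavlovian odor conditioning, built around the
    question of whether a population encodes odor identity, reward
    contingency (valence), or licking vigor. Provides a synthetic-session
    simulator with controllable ground-truth encoding structure
    (GCaMP-like transients on a drifting baseline, trial metadata, and
    behavior channels), moving-baseline dF/F estimation with a Gaussian
    mixture model, trial alignment and windowed response statistics,
    frame-wise responsiveness testing with Holm familywise error control,
    single-neuron pairwise auROC discriminability with permutation nulls
    and quadrant categorization, cross-validated population decoders with
    cross-pair generalization and PCA-restricted variants,
    participation-ratio dimensionality, Ward hierarchical clustering of
    response profiles, and regression analyses decoupling reward
    contingency from licking vigor. Results are returned as tibbles ready
    for dplyr/ggplot2 workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
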