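Package: cophos
Title: Kinase-Substrate Association Prediction from Co-Phosphorylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts kinase-substrate associations from mass-spectrometry
    phosphoproteomics by mining correlated phosphorylation
    ("co-phosphorylation") of phosphosites across biological states. Builds a
    complete weighted network over measured phosphosites using biweight
    midcorrelation (or Pearson correlation), fits empirical tail models for
    the background and shared-kinase pair distributions, and scores candidate
    kinases for every measured site with a naive Bayes log-likelihood ratio.
    Optionally integrates a static (sequence/interaction-based) kinase-site
    score table into a combined score. Includes permutation null models with
    Kolmogorov-Smirnov comparisons, sample-dimension adequacy diagnostics,
    leave-one-out cross-validation with top-k metrics, cross-dataset
    reproducibility and multi-dataset consensus reports, a latent-factor
    synthetic data generator for end-to-end testing, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
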