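Package: ecggan
Title: Generative Adversarial Synthesis and Evaluation of 12-Lead ECGs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for generating synthetic 10-second 12-lead
    electrocardiograms with 1D generative adversarial networks and for
    evaluating them at cohort scale. Provides exact conversion between the
    8-independent-channel storage representation and the clinical 12 leads,
    two generator architectures (an up-sampling deconvolution generator and
    a 1D U-net with skip concatenation) sharing a phase-shuffle critic
    trained under the Wasserstein objective with gradient penalty, a
    dynamical PQRST simulator that emulates a normal-population ECG cohort,
    a transparent rule-based normality screener, and cohort summaries
    (fraction classified normal, interval and amplitude tables, QT/RR
    coupling). Networks run on a small built-in reverse-mode
    differentiation engine so that training, including double
    backpropagation through the gradient penalty, needs no external
    deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
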