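Package: ictonet
Title: Brain Network Ictogenicity from Peri-Ictal Multichannel Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the seizure-generating propensity (brain network
    ictogenicity, BNI) of functional networks inferred from multichannel
    peri-ictal electrophysiology. Provides preprocessing (resampling, median
    re-referencing, zero-phase band-pass and notch filtering, peri-ictal
    segmentation), surrogate-corrected functional connectivity via iterated
    amplitude adjusted Fourier transform (IAAFT) surrogates with zero-lag
    Pearson correlation or the nonlinear h2 index, simulation of noisy
    theta-neuron dynamics on the inferred networks, coupling-integrated BNI
    time courses, in-silico resection (delta BNI), cohort-level statistics
    (Kruskal-Wallis, per-subject one-tailed rank tests, permutation
    chi-square, ROC/AUC with half-split comparison), and a ground-truthed
    synthetic cohort generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
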