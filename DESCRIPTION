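Package: affecthmm
Title: Population-Level Hidden Markov Modelling of Cross-Sectional Well-Being Submissions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian-emission hidden Markov modelling of chronologically
    ordered, anonymous 7-item well-being (SWEMWBS) submissions. Provides
    data cleaning and time binning, a seeded synthetic-data generator with
    latent-state ground truth, from-scratch Baum-Welch estimation with BIC
    state-count selection and Viterbi decoding, transition-dynamics
    summaries (stationary distribution, dwell times, row entropies,
    bootstrap confidence intervals), morning/afternoon contingency analysis
    (Pearson chi-square, Cramer's V), PCA state-separability projection,
    and an end-to-end reporting pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
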