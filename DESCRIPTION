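Package: pdspeech
Title: Acoustic Assessment of Hypokinetic Dysarthria in Mandarin-Speaking
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative acoustic assessment of Parkinson's
    disease speech from four standard paradigms: sustained vowels
    (/a/, /i/, /u/), fast /pa/ diadochokinesis, fast /i/-/u/ alternation,
    and passage reading. Extracts 29 established features (F0 statistics,
    perturbation measures, harmonics-to-noise ratio, LPC formants and
    vowel space area, syllable rate and voice onset time, pause metrics
    and net speech rate), performs gender-stratified z-normalization
    against healthy controls, group comparisons with Hedges' g effect
    sizes and FDR correction, covariate-adjusted partial correlations,
    Hoehn-Yahr stage comparisons, and Gaussian naive Bayes classification
    with cross-validated ROC/AUC. Also computes graph-theoretic metrics
    (clustering, nodal and local efficiency) on functional connectivity
    networks, and ships fully seeded synthetic-speech and cohort
    generators with exact ground truth so the whole pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    tibble,
    dplyr,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
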