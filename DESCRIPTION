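Package: neoegg
Title: Spectral and Time-Frequency Analysis of Neonatal Electrogastrography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify gastric slow-wave activity from cutaneous
    electrogastrography (EGG) recordings of neonates around enteral feeds.
    Implements the full analysis chain: signal conditioning (decimation,
    polynomial detrending, zero-phase low-pass filtering), derivation of
    pre-/during-/post-feed analysis windows from feed timing, Welch power
    spectral density with spectral means over the bradygastria, normogastria
    and tachygastria rhythm bands (mPSD), continuous wavelet transform
    spectrograms with cone-of-influence masking, per-minute dominant-rhythm
    partition maps and percent time spent in each gastric rhythm, and
    cohort-level statistics (one-way ANOVA with Tukey post-hoc contrasts and
    linear regression against gestational age). A synthetic-cohort simulator
    with Markov regime switching between rhythm bands provides ground-truth
    recordings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
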