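Package: bfcoh
Title: Basalo-Cortical Gamma Coherence and Cholinergic Unit Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous basal-forebrain and cortical
    silicon-probe recordings: Morlet wavelet spectrograms and smoothed wavelet
    coherence between field-potential channels, behavior-epoch coherence change
    scores with Monte-Carlo permutation significance maps, one-way ANOVA with
    Tukey HSD comparisons of relative coherence, spike-unit physiology
    (trough-to-peak latency, burst index, waveform PCA, k-means and bagged-tree
    classification), optogenetic tagging of cholinergic units, cross-correlogram
    detection of putative monosynaptic connections against a convolved Poisson
    baseline, and spike-triggered cortical gamma-power analysis with
    Kolmogorov-Smirnov tests. Includes a seeded statistical generator of
    synthetic multichannel recordings with injected ground-truth effects for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
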