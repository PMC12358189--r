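Package: spikedc
Title: Spike Sorting and Evoked-Response Analysis for Direct-Current
    Nerve Conduction Block Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-electrode extracellular recordings of
    spinal responses to natural hindpaw stimulation under peripheral direct
    current (DC) neuromodulation. Provides a ground-truth synthetic recording
    generator, band-pass filtering and threshold spike detection, PCA/k-means
    template clustering with inter-spike-interval contamination refinement,
    data-driven peristimulus response-window derivation, evoked-response
    classification, mixed-model estimation of DC-mediated percent reduction
    with estimated marginal means, post-DC recovery-time analysis, and a
    Hartigans' dip test for latency unimodality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    boot,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
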