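Package: cracm
Title: Analysis of Channelrhodopsin-Assisted Circuit Mapping Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-cell current-clamp recordings from
    optogenetic circuit-mapping (CRACM) experiments on cortical interneurons.
    Extracts intrinsic electrophysiological properties (resting potential,
    input resistance, membrane time constant, sag index, rheobase, action
    potential threshold/width/afterhyperpolarization, spike-frequency
    adaptation) from current-step sweeps, detects and quantifies light-evoked
    monosynaptic EPSPs with threshold-intensity and responsiveness calls,
    classifies somatostatin interneuron subtypes with a k-nearest-neighbour
    classifier, models response incidence by stepwise logistic regression with
    McFadden's pseudo-R-squared, runs normality-gated two-group comparisons and
    two-way ANOVA, and performs injection-specificity quality control from
    laminar fluorescence depth profiles. A seeded synthetic patch-clamp
    generator provides ground-truth recordings for validation, so the full
    pipeline can be exercised without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    car,
    class,
    withr
Config/testthat/edition: 3
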