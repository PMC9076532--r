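Package: placegate
Title: Engagement-Gated Hippocampal Place-Code Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for studying how hippocampal place codes
    depend on behavioral task engagement during virtual-reality navigation.
    Provides a synthetic session generator for a 2-m circular track task
    with standard/probe/crutch trials and engagement streaks, fluorescence
    trace preprocessing (neuropil correction, rolling-percentile dF/F,
    Gaussian temporal smoothing), lick-based engagement classification by
    k-means, place-field detection against a circular-shift shuffle null
    with reliability and selectivity metrics, and Poisson naive-Bayes
    position decoding with sliding-window, engagement-split, speed-matched
    and streak-onset protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rhdf5
Config/testthat/edition: 3
RoxygenNote: 7.3.3
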