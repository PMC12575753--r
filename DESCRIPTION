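Package: avdelay
Title: Audiovisual Delay Tuning, Multisensory Integration and Spike-Train
    Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of extracellular spike-train recordings from audiovisual
    stimulation experiments in the superior colliculus and similar structures:
    peristimulus time histograms, permutation-based responsiveness testing and
    neuron taxonomy (visual, auditory, bimodal, gated), spatial receptive-field
    mapping with 2D Gaussian fits, audiovisual delay-tuning statistics
    (specificity, firing-rate modulation, reliability, multisensory interaction
    indices and linear-sum delay prediction), population decoding of
    audiovisual delay with synthetic shifted-auditory and linear-sum control
    trials, jitter-corrected cross-correlogram inference of putative
    connections, and a hierarchical bootstrap for nested (animal/session/
    neuron) data.  Includes an inhomogeneous Bernoulli spike-train simulator
    emulating the stimulation protocols with known ground truth, so every
    analysis stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    kernlab,
    randomForest,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
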