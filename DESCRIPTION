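Package: striatpot
Title: Peri-Stimulus Time Histogram Analysis of Sensory-Reinforced
    Corticostriatal Potentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Block-wise peri-stimulus time histogram (PSTH) analysis of
    multi-unit striatal spike trains evoked by single-pulse motor cortex
    stimulation.  Implements threshold-based evoked-response detection and
    per-subject normalization, multichannel potentiation-peak detection with
    consecutive-block channel classification, a randomization F test for
    drug effects on baseline responding, and a chi-square comparison of
    potentiated-channel proportions.  A synthetic-data generator emulates
    jittered stimulation trains, Poisson multi-unit background firing,
    latency-structured evoked responses and gated potentiation, so every
    stage of the pipeline can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
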