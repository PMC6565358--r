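Package: surpriseERP
Title: Cued Serial-Pattern Task Simulation, Bayesian Surprise and EEG Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a cued serial-pattern detection
    paradigm with blockwise manipulation of irreducible uncertainty. Generates
    task sessions with checkpoint (CP), prediction-error (PE) and standard (STD)
    event labels, computes ideal-Bayesian-observer surprise for sequence
    outcomes, scores behavioural responses (onset/offset latencies, PR index,
    repeated-measures ANOVA, performance-based subgroup analyses), simulates
    synthetic participants (reaction times and 62-channel ERP epochs),
    preprocesses multichannel epochs (filtering, artifact rejection, channel
    interpolation, average reference), runs repeated-measures cluster-mass
    permutation tests over channel-by-time grids, and segments group ERPs into
    topographic microstates via atomize-and-agglomerate hierarchical clustering
    (AAHC) with map-count selection, back-fitting and segment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    signal,
    e1071,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
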